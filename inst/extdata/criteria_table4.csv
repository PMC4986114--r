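id,label,category
A1,The existence of the pharmacoeconomy assessment,economic
A2,Announcement of the incremental cost effectiveness (ICER) of a new drug,economic
A3,Impact budget,economic
A4,Reasonableness of increasing insurance costs due to acceptance of new drug,economic
A5,Being a reasonable price of a new drug,economic
A6,Sales volume of the new drug in society covered by the insurance not be more than the current volume,economic
A7,Domestic production of a new drug,managerial
A8,The existence of physician demand,managerial
A9,"Declining the cost of medical services (by reducing the use of other hospital services, para-clinical and more)",economic
A10,Make the most of living healthier,clinical
A11,"Threshold setting about the new drug cost effectiveness (for example, 16 thousand USD for one year of healthy life)",economic
A12,The existence of a proper clinical trial evidence to determine the effectiveness of the new drug,evidence_quality
A13,Assurance of the increased survival,clinical
A14,Prevent death and further disability,clinical
A15,Effectiveness of new drugs,clinical
A16,Safety of new drugs,clinical
A17,Considerable decreasing the number of patients recovered by new drug,clinical
A18,The existence of comparable medication,clinical
A19,Being vital medication,clinical
A20,Conducting age-targeting,clinical
A21,Specifying target population,clinical
A22,The ability to help in the reduction of health hazards by the new drug,clinical
A23,Public health promotion,clinical
A24,The new drug benefit for other applications (other indications),clinical
A25,Be effective in reducing other interventions,clinical
A26,Much easier to use a new drug,clinical
A27,Shorter use duration of the drug in comparison with the similar drug,clinical
A28,Accomplish cost-effectiveness study for new drugs entering to insurance list,economic
A29,Independence of assessment group,evidence_quality
A30,The high quality of the scientific literature reviewed in the study,evidence_quality
A31,Determination the validity of the economic model,evidence_quality
A32,"Assessment of the viewpoint of stakeholders (patients, pharmaceutical companies, insurers, government and society) in the study",evidence_quality
A33,Determination of the degree of uncertainty in economic evaluation studies,evidence_quality
A34,Consideration of health technology assessment (HTA),evidence_quality
A35,Recently published study of a new drug,evidence_quality
A36,The characteristics of drug use in low income deciles,managerial
A37,The existence of a history of drug use in similar situation countries to us,managerial
A38,Observe the ethical considerations (rule of rescue),managerial
A39,The existence of a positive opinion of manager(s) to accept new drug,managerial
A40,Assurance of continuous availability of new drug,managerial
A41,The drug is in priorities of disease treatment,managerial
A42,The drug is in priorities of disease screening,managerial
A43,The drug is in priorities of disease diagnosis,managerial
A44,The drug is in priorities of disease prevention,managerial
A45,The existence of favorable comments of the expert committee in the process of the admissions decision for medicine,managerial
A46,Providing a rational response for decision report to people,managerial
A47,Providing a rational response to the revise decision,managerial
A48,Having a history and previous drug assessment at the council reviews of the insurer,managerial
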