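id,closeness_published,rank_published,d_plus_published,d_minus_published
A7,0.556,1,0.034,0.042
A27,0.399,2,0.042,0.028
A29,0.363,3,0.045,0.026
A3,0.362,4,0.045,0.025
A37,0.358,5,0.045,0.025
A16,0.354,6,0.045,0.025
A15,0.352,7,0.045,0.025
A48,0.351,8,0.045,0.024
A6,0.352,9,0.045,0.023
A39,0.337,10,0.045,0.023
A1,0.334,11,0.047,0.023
A45,0.333,12,0.045,0.023
A18,0.332,13,0.046,0.023
A26,0.326,14,0.046,0.022
A8,0.323,15,0.044,0.021
A10,0.322,16,0.047,0.022
A14,0.322,17,0.046,0.022
A19,0.318,18,0.046,0.021
A5,0.318,19,0.047,0.022
A21,0.315,20,0.046,0.021
A41,0.314,21,0.046,0.021
A40,0.310,22,0.047,0.021
A13,0.309,23,0.047,0.021
A12,0.308,24,0.046,0.021
A2,0.306,25,0.048,0.021
A4,0.305,26,0.045,0.020
A28,0.302,27,0.047,0.020
A22,0.297,28,0.047,0.019
A20,0.284,29,0.047,0.019
A34,0.281,30,0.047,0.019
A11,0.279,31,0.049,0.019
A36,0.276,32,0.048,0.018
A23,0.276,33,0.048,0.018
A17,0.271,34,0.049,0.018
A38,0.269,35,0.047,0.017
A47,0.266,36,0.047,0.018
A30,0.251,37,0.048,0.016
A25,0.249,38,0.049,0.016
A44,0.241,39,0.051,0.016
A9,0.236,40,0.050,0.016
A33,0.231,41,0.050,0.015
A31,0.227,42,0.050,0.015
A46,0.227,43,0.050,0.015
A35,0.223,44,0.050,0.014
A42,0.215,45,0.052,0.014
A24,0.214,46,0.050,0.014
A43,0.212,47,0.052,0.014
A32,0.208,48,0.050,0.013
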