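Package: topsisHTA
Title: TOPSIS-Based Consensus Ranking of Drug Reimbursement Criteria
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Implements a two-stage consensus model for deciding which drugs
    enter a basic health-insurance reimbursement list. Stage one screens
    candidate criteria from an expert panel's 1-100 importance scores using a
    mean/standard-deviation exclusion rule and assesses questionnaire
    reliability with Cronbach's alpha. Stage two ranks the surviving criteria
    with the Technique for Order Preference by Similarity to an Ideal Solution
    (TOPSIS) over four fixed sub-criteria scored on a 5-point Likert scale,
    converts ranks to points, and applies a half-of-total points threshold to
    recommend or reject a candidate drug. Ships the published criteria catalog
    and result tables as fixtures, a consistency validator for those tables,
    a seeded synthetic panel generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
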