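Package: psadens
Title: PSA Derivatives and Race/Ethnicity-Stratified Cutoffs for
    Significant Low-Grade Prostate Tumor Volume
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting significant Gleason score 3+3=6
    (Grade Group 1) prostate tumor volume (>= 0.5 cm^3) from serum PSA
    and its derivatives: PSA density (PSAD), PSA mass (PSAM) and PSA
    mass density (PSAMD). Provides the derivative calculators (body
    surface area, plasma volume, hemodilution-adjusted PSA mass),
    surname-based Hispanic ethnicity assignment with race-code
    exclusions (NHIA), race/ethnicity-stratified ROC analysis with
    upper-left optimal cutoff selection and fixed-specificity
    sensitivity comparison, cohort summary and association statistics,
    and a seeded synthetic-cohort generator emulating a two-institution
    radical-prostatectomy series so the whole pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
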