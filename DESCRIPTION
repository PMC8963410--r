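Package: dynpract
Title: Dynamic-Practice Modeling of Vasopressor Initiation in Septic Shock
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for statistically characterizing "usual care" around
    vasopressor initiation in hypotensive septic emergency-department (ED)
    patients. Provides a synthetic longitudinal encounter generator with a
    known clinician decision policy, outcome classification by vasopressor
    course duration and initiation location, longitudinal feature engineering
    (exponentially weighted vitals, running extrema, fluid accounting,
    carry-forward and median imputation), a two-stage covariate selection
    pipeline (L1-regularized screen followed by stepwise forward selection)
    for a usual-care logistic model, ROC evaluation with DeLong confidence
    intervals and paired comparisons, leave-one-out cross-validation, a
    temporal validation experiment, score-distribution comparisons between
    patient cohorts, and a high-specificity threshold-crossing analysis of
    vasopressor timing outliers and interim intravenous-fluid volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    pROC,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
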