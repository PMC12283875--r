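Package: kneecast
Title: Two-Stage Ordinal Prediction of Knee Osteoarthritis Severity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts 8-year knee osteoarthritis severity (healthy KL01,
    moderate KL2, severe KL34) from baseline tabular predictors with a
    two-stage cascade of class-balanced bagged tree ensembles. Provides
    cohort eligibility filtering for longitudinal knee data, outcome
    re-categorisation from Kellgren-Lawrence follow-up trajectories,
    subject-grouped stratified repeated k-fold cross-validation,
    imbalance-aware metrics (balanced accuracy, weighted F1), the
    corrected repeated k-fold CV t-test for model comparison, and a
    seeded synthetic cohort generator for end-to-end testing without
    access-restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ranger,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rpart,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
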