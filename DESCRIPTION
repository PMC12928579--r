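Package: fairaudit
Title: Fairness and Adversarial-Robustness Auditing of Binary Clinical Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An audit pipeline for binary clinical classifiers on tabular cohort
    data. Generates synthetic Parkinson's-disease-like cohorts with controllable
    demographic skew and planted outcome bias, runs a deterministic preprocessing
    pipeline (cleaning, missingness filtering, median/mode imputation, min-max
    normalization, sensitive-attribute binarization, stratified splitting),
    selects features by correlation-aware recursive importance ranking, trains
    seeded tree and neural baselines, computes per-group confusion rates and the
    standard group-fairness metrics (statistical parity difference, disparate
    impact, equal opportunity difference, average absolute odds difference),
    learns an optimized pre-processing fairness transformation as a linear
    program, and stress-tests training data with stratified label-flipping
    poisoning and sensitive-attribute label-leakage attacks, reporting
    repeated-run means, standard deviations, and paired t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    quadprog,
    rpart,
    ranger,
    nnet,
    xgboost
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
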