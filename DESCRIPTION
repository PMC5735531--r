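Package: sparsescreen
Title: Sparse Model Selection for Behavioral Screening Score Sheets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-phase sparse model-selection pipeline for item-level
    behavioral screening instruments such as the Autism Diagnostic
    Observation Schedule (ADOS). Encodes missing answers as indicator
    features, runs an L0-penalized nested grid search with stratified
    cross-validation over a registry of 17 classifier configurations in
    five families, applies the one-standard-error parsimony rule, builds
    cross-classifier feature-usage heatmaps, derives consensus reduced
    feature sets with the documented tie-breaking rule, and retrains and
    evaluates the reduced models on a held-out partition. Ships a
    synthetic score-sheet generator with planted informative items,
    configurable missingness and severe class imbalance so the whole
    pipeline is testable without access-restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    graphics,
    jsonlite,
    kernlab,
    ranger,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
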