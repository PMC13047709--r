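Package: sdmflow
Title: Ensemble Species Distribution Modelling with Habitat-Change and
    Climate-Anomaly Accounting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale ensemble species distribution modelling (SDM)
    pipeline: occurrence thinning, pseudo-absence sampling with prevalence
    weighting, permutation-importance and Pearson-correlation predictor
    screening, a registry of presence/background learners including a
    natively implemented penalized maxent-style model with regularization
    multiplier by feature class tuning under AICc, AUC/TSS evaluation with
    a repetition protocol, TSS-weighted ensembling gated on member skill,
    habitat suitability grading with change and transition accounting, and
    multivariate environmental similarity surface (MESS) analysis with
    most-dissimilar-variable maps. Ships a synthetic-landscape generator
    with a known truth surface so the full workflow is testable end to end
    without external rasters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    glmnet,
    jsonlite,
    mgcv,
    nnet,
    purrr,
    randomForest,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
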