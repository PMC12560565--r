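Package: psapredict
Title: Individualized Treatment-Response Prediction for Psoriatic Arthritis Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for developing and evaluating clinical prediction
    models of treatment response in four-arm psoriatic arthritis trials.
    Simulates trial cohorts with a known logistic outcome model, computes the
    minimal disease activity (MDA) responder outcome at week 16, screens
    log/square-root transformations for skewed baseline predictors, selects
    predictors by elastic net in the full cohort and treatment subgroups,
    fits homogeneous, risk-modelling (linear-predictor by treatment
    interaction) and effect-modelling Ridge strategies, evaluates them by
    nested leave-one-out cross-validated AUC-ROC, and produces per-patient
    counterfactual comparisons of predicted response probability between
    tofacitinib and the stratum comparator treatment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet
Config/testthat/edition: 3
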