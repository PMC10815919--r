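Package: bayeslos
Title: Hierarchical Bayesian Length-of-Stay Modelling for Cardiac Surgery Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling hospital length of stay (LoS) of cardiac
    surgery patients from pre-operative clinical variables. Provides a
    calibrated synthetic cohort generator (marginal-calibrated and
    model-faithful modes), a leakage-free preprocessing pipeline (reference
    imputation, label encoding, min-max scaling fitted on training rows),
    permutation feature importance selection, simple and hierarchical
    Bayesian truncated-normal regression fitted by a compiled blocked Gibbs
    sampler with convergence diagnostics, eight frequentist baseline
    regressors, and an evaluation suite (RMSE, MAE, dispersion statistics,
    adjusted R-squared, Taylor-diagram statistics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp,
    ranger,
    glmnet,
    xgboost,
    e1071,
    MASS
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    rjags,
    withr,
    coda
Config/testthat/edition: 3
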