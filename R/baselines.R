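# Allowed hyperparameter names per baseline; fit_baseline() validates
# configs against this schema before dispatching to a backend.
baseline_schema <- list(
  sgd_linear = c("learning_rate", "inverse_scaling_factor", "regularization",
                 "eta0", "max_iter"),
  huber = "k",
  gradient_boosted_trees = c("subsample", "n_estimators", "min_samples_split",
                             "min_samples_leaf", "min_child_weight",
                             "max_features", "max_depth", "learning_rate",
                             "colsample_bytree", "booster", "alpha", "lambda"),
  random_forest = c("n_estimators", "min_samples_split", "min_samples_leaf",
                    "max_features", "max_depth", "bootstrap"),
  lasso = "lambda",
  ridge = "lambda",
  svr_poly = c("kernel", "degree", "regularization"),
  ols = character()
)

#' Packaged baseline configurations
#'
#' Reads the reference hyperparameter set of the eight frequentist baseline
#' regressors shipped with the package (`inst/extdata/baselines.yaml`).
#'
#' @return Named list of per-model hyperparameter lists, in the canonical
#'   model order.
#' @export
baseline_configs <- function() {
  cfg <- yaml::read_yaml(system.file("extdata", "baselines.yaml", package = "bayeslos"))
  purrr::map(cfg, ~ if (is.null(.x)) list() else .x)
}

#' Model identifiers of the baseline suite
#' @return Character vector of the eight model ids in canonical order.
#' @export
baseline_ids <- function() names(baseline_schema)

validate_config <- function(model_id, config) {
  if (!model_id %in% names(baseline_schema)) {
    abort(paste0("Unknown baseline model id: ", model_id))
  }
  unknown <- setdiff(names(config), baseline_schema[[model_id]])
  if (length(unknown)) {
    abort(paste0("Unknown hyperparameter(s) for `", model_id, "`: ",
                 paste(unknown, collapse = ", ")))
  }
  config
}

#' Fit one baseline and predict the test set
#'
#' Trains the requested frequentist regressor with the configured
#' hyperparameters and seed and returns unrounded test predictions (days).
#' Backends: penalized SGD linear regression (compiled, sklearn-style
#' schedules), Huber M-estimation ([MASS::rlm()]), gradient boosted trees
#' ([xgboost::xgb.train()]), random forest ([ranger::ranger()]), lasso and
#' ridge ([glmnet::glmnet()]), polynomial-kernel epsilon-SVR
#' ([e1071::svm()]) and ordinary least squares ([stats::lm()]).
#'
#' @param model_id One of [baseline_ids()].
#' @param X_train,X_test Numeric design matrices/tibbles (scaled, complete).
#' @param y_train Training target (days).
#' @param config Hyperparameter list; defaults to the packaged configuration.
#' @param seed Integer seed.
#' @return Numeric vector of test predictions.
#' @export
fit_baseline <- function(model_id, X_train, y_train, X_test,
                         config = NULL, seed = 1L) {
  config <- validate_config(model_id, config %||% baseline_configs()[[model_id]])
  Xtr <- as.matrix(X_train)
  Xte <- as.matrix(X_test)[, colnames(Xtr), drop = FALSE]
  y <- as.numeric(y_train)
  n <- nrow(Xtr)
  p <- ncol(Xtr)
  if (p == 1 && model_id %in% c("lasso", "ridge")) {
    # glmnet requires >= 2 columns; a zero pad leaves the fit unchanged
    Xtr <- cbind(Xtr, .pad = 0)
    Xte <- cbind(Xte, .pad = 0)
  }

  switch(
    model_id,
    sgd_linear = with_seed(seed, {
      coefs <- .sgd_fit(
        Xtr, y,
        alpha = config$regularization %||% 0.890,
        eta0 = config$eta0 %||% 0.01,
        power_t = config$inverse_scaling_factor %||% 0.899,
        schedule = config$learning_rate %||% "adaptive",
        max_iter = as.integer(config$max_iter %||% 200),
        tol = 1e-5
      )
      drop(coefs[1] + Xte %*% coefs[-1])
    }),
    huber = {
      # rlm refuses singular designs; training-constant columns carry no
      # information and are excluded from the M-estimation
      keep <- apply(Xtr, 2, function(col) length(unique(col)) > 1)
      fit <- MASS::rlm(cbind(`(Intercept)` = 1, Xtr[, keep, drop = FALSE]), y,
                       psi = MASS::psi.huber, k = config$k %||% 4,
                       maxit = 100)
      drop(cbind(1, Xte[, keep, drop = FALSE]) %*% coef(fit))
    },
    gradient_boosted_trees = {
      dtr <- xgboost::xgb.DMatrix(Xtr, label = y, nthread = 1)
      fit <- xgboost::xgb.train(
        params = list(
          booster = config$booster %||% "gbtree",
          eta = config$learning_rate %||% 0.01,
          max_depth = as.integer(config$max_depth %||% 68),
          subsample = config$subsample %||% 0.8,
          colsample_bytree = config$colsample_bytree %||% 0.2,
          min_child_weight = config$min_child_weight %||% 6,
          alpha = config$alpha %||% 0.8,
          lambda = config$lambda %||% 0.8,
          nthread = 1, seed = seed
        ),
        data = dtr, nrounds = as.integer(config$n_estimators %||% 1800),
        verbose = 0
      )
      predict(fit, xgboost::xgb.DMatrix(Xte, nthread = 1))
    },
    random_forest = {
      fit <- ranger::ranger(
        x = as.data.frame(Xtr), y = y,
        num.trees = as.integer(config$n_estimators %||% 1200),
        min.node.size = as.integer(config$min_samples_leaf %||% 4),
        mtry = max(1L, floor(sqrt(p))),
        max.depth = as.integer(config$max_depth %||% 20),
        replace = !isFALSE(config$bootstrap),
        sample.fraction = 1,
        seed = seed, num.threads = 1
      )
      predict(fit, data = as.data.frame(Xte), num.threads = 1)$predictions
    },
    lasso = {
      if (var(y) == 0 || all(apply(Xtr, 2, var) == 0)) {
        return(rep(mean(y), nrow(Xte)))
      }
      fit <- glmnet::glmnet(Xtr, y, alpha = 1,
                            lambda = config$lambda %||% 0.01,
                            standardize = FALSE, thresh = 1e-10)
      drop(predict(fit, Xte))
    },
    ridge = {
      if (var(y) == 0 || all(apply(Xtr, 2, var) == 0)) {
        return(rep(mean(y), nrow(Xte)))
      }
      # Penalty on the RSS scale; glmnet's per-observation objective needs
      # lambda / n for the same optimum.
      fit <- glmnet::glmnet(Xtr, y, alpha = 0,
                            lambda = (config$lambda %||% 1.08) / n,
                            standardize = FALSE, thresh = 1e-12)
      drop(predict(fit, Xte))
    },
    svr_poly = {
      # a constant target has no support vectors: the epsilon-SVR optimum
      # is the constant itself
      if (var(y) == 0) return(rep(y[1], nrow(Xte)))
      fit <- e1071::svm(Xtr, y, type = "eps-regression",
                        kernel = "polynomial",
                        degree = as.integer(config$degree %||% 2),
                        cost = config$regularization %||% 0.3,
                        scale = FALSE)
      unname(predict(fit, Xte))
    },
    ols = {
      df <- as.data.frame(Xtr)
      fit <- lm(y ~ ., data = cbind(y = y, df))
      unname(predict(fit, as.data.frame(Xte)))
    }
  )
}

#' Run the full baseline suite
#'
#' Fits all eight baselines in the canonical order with per-model seeds
#' derived deterministically from the master seed. A failure in any single
#' model aborts with the model named.
#'
#' @inheritParams fit_baseline
#' @param seed Master seed.
#' @param configs Optional named list of per-model configs (defaults to the
#'   packaged ones).
#' @return Named list (model id -> numeric prediction vector), in canonical
#'   order.
#' @export
run_baselines <- function(X_train, y_train, X_test, seed = 1L, configs = NULL) {
  configs <- configs %||% baseline_configs()
  ids <- baseline_ids()
  out <- purrr::imap(setNames(ids, ids), function(id, nm) {
    tryCatch(
      fit_baseline(id, X_train, y_train, X_test,
                   config = configs[[id]],
                   seed = derive_seed(seed, match(id, ids))),
      error = function(e) {
        abort(paste0("Baseline `", id, "` failed: ", conditionMessage(e)))
      }
    )
  })
  out
}
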