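#' Inner split of the training set
#'
#' Partitions the main training indices again at the same ratio, producing
#' the fit set for the permutation-importance base model and the held-out
#' validation set on which importances are scored.
#'
#' @param train Integer vector of training row indices.
#' @param fraction Fit fraction (the fit size is `round(fraction * |train|)`).
#' @param seed Integer seed.
#' @return A list with sorted integer `fit` and `validate` index vectors.
#' @export
inner_split <- function(train, fraction = 0.8, seed = 1L) {
  if (length(train) < 10) abort("Need at least 10 training rows for an inner split.")
  take <- round(fraction * length(train))
  fit <- with_seed(seed, sort(sample(train, take)))
  list(fit = fit, validate = setdiff(train, fit))
}

#' Fit the permutation-importance base model
#'
#' Trains a seeded random forest regressor on the fit portion of the training
#' data. The returned handle exposes `predict()`.
#'
#' @param X A numeric tibble/data frame of features (no missing values).
#' @param y Numeric target vector (days).
#' @param seed Integer seed.
#' @param num_trees Number of trees.
#' @param ... Further arguments passed to [ranger::ranger()].
#' @return An object of class `los_base_model`.
#' @export
fit_base_model <- function(X, y, seed = 1L, num_trees = 500, ...) {
  X <- as.data.frame(X)
  if (nrow(X) < 2) abort("Need at least 2 rows to fit the base model.")
  fit <- ranger::ranger(
    x = X, y = y, num.trees = num_trees, seed = seed,
    num.threads = 1, ...
  )
  structure(list(fit = fit, features = names(X)), class = "los_base_model")
}

#' @export
predict.los_base_model <- function(object, newdata, ...) {
  predict(object$fit, data = as.data.frame(newdata), num.threads = 1)$predictions
}

#' Permutation importance of a single feature
#'
#' Replaces the feature's validation column by `K` seeded random permutations
#' of its own observed values -- a draw from the exact empirical marginal that
#' severs the link to the outcome -- and returns the mean increase in
#' validation RMSE over the unpermuted baseline. A positive score means the
#' feature contributes to accuracy; a constant column scores exactly 0.
#'
#' @param model A fitted regressor exposing `predict()` (e.g.
#'   [fit_base_model()] output).
#' @param X_val Validation features (tibble/data frame).
#' @param y_val Validation target.
#' @param feature Feature name.
#' @param K Number of permutation repetitions (`>= 1`).
#' @param seed Integer seed.
#' @return The importance score in days of RMSE.
#' @export
pfi_score <- function(model, X_val, y_val, feature, K = 10, seed = 1L) {
  report <- permutation_importance(model, X_val, y_val, K = K, seed = seed,
                                   features = feature)
  report$importance[report$feature == feature]
}

#' Permutation feature importance report
#'
#' Computes the baseline validation RMSE once, then the permutation
#' importance of every feature (see [pfi_score()]) against that shared
#' baseline.
#'
#' @inheritParams pfi_score
#' @param features Feature names to score (defaults to all columns of
#'   `X_val`).
#' @return A tibble of class `los_importance` with columns `feature`, `K`,
#'   `baseline_score`, `mean_augmented_score`, `importance` and `selected`
#'   (`importance > 0`).
#' @export
permutation_importance <- function(model, X_val, y_val, K = 10, seed = 1L,
                                   features = NULL) {
  if (K < 1) abort("`K` must be at least 1.")
  X_val <- as.data.frame(X_val)
  features <- features %||% names(X_val)
  unknown <- setdiff(features, names(X_val))
  if (length(unknown)) {
    abort(paste0("Feature(s) not in the matrix: ", paste(unknown, collapse = ", ")))
  }
  baseline <- rmse(y_val, predict(model, X_val))
  rows <- purrr::imap(setNames(features, features), function(f, nm) {
    scores <- with_seed(derive_seed(seed, match(f, names(X_val))), {
      vapply(seq_len(K), function(k) {
        Xp <- X_val
        Xp[[f]] <- sample(Xp[[f]])
        rmse(y_val, predict(model, Xp))
      }, numeric(1))
    })
    tibble::tibble(
      feature = f, K = as.integer(K), baseline_score = baseline,
      mean_augmented_score = mean(scores),
      importance = mean(scores) - baseline
    )
  })
  out <- dplyr::bind_rows(rows)
  out$selected <- out$importance > 0
  class(out) <- c("los_importance", class(out))
  out
}

#' Select the positively contributing features
#'
#' Keeps the features whose permutation importance exceeds the floor
#' (strictly positive by default), ordered by decreasing importance with
#' alphabetical tie-breaks.
#'
#' @param report A `los_importance` tibble.
#' @param floor Minimum importance (exclusive); defaults to 0.
#' @return Character vector of selected feature names.
#' @export
select_features <- function(report, floor = 0) {
  if (is.null(report) || nrow(report) == 0) abort("Empty importance report.")
  kept <- report[report$importance > floor, , drop = FALSE]
  kept <- kept[order(-kept$importance, kept$feature, method = "radix"), , drop = FALSE]
  kept$feature
}

#' Packaged reference feature list
#'
#' The 44 pre-operative variables retained by the permutation-importance
#' screen on the reference registry cohort, shipped with the package so
#' replication runs can be built on the identical feature set.
#'
#' @return Character vector of 44 feature names.
#' @export
los_selected_features <- function() {
  readLines(system.file("extdata", "selected_features.txt", package = "bayeslos"))
}

#' @export
print.los_importance <- function(x, ...) {
  cat("<los_importance>", nrow(x), "features, baseline RMSE",
      format(x$baseline_score[1], digits = 4), "days,",
      sum(x$selected), "selected\n")
  NextMethod()
}

#' @importFrom ggplot2 autoplot
#' @export
autoplot.los_importance <- function(object, top = 30, ...) {
  df <- dplyr::slice_max(object, .data$importance, n = top)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$importance,
    y = stats::reorder(.data$feature, .data$importance),
    fill = .data$selected
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "Permutation importance (days of validation RMSE)",
      y = NULL, fill = "Selected"
    ) +
    ggplot2::theme_minimal()
}
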