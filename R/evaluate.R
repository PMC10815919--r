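#' Summary statistics for one model's test predictions
#'
#' Computes the comparison-table statistic set: mean, sample standard
#' deviation, rounded minimum and maximum, coefficient of variation
#' (sd / mean), adjusted R-squared (x 100), RMSE and MAE. Sample (n - 1)
#' standard deviations are used throughout; a negative adjusted R-squared
#' marks a fit worse than the constant-mean predictor.
#'
#' @param actual Observed test LoS (days).
#' @param predicted Model predictions (days), same length and record order.
#' @param p Number of model features (for the adjusted R-squared degrees of
#'   freedom); must satisfy `p < n - 1`.
#' @return A one-row tibble with `mean`, `sd`, `min`, `max`, `cv`,
#'   `adj_r_squared`, `rmse`, `mae`.
#' @examples
#' compute_metrics(c(1, 2, 5), c(1, 2, 3), p = 1)
#' @export
compute_metrics <- function(actual, predicted, p) {
  n <- length(actual)
  if (length(predicted) != n) abort("`actual` and `predicted` differ in length.")
  if (n < 2) abort("Need at least 2 records.")
  if (p >= n - 1) abort("`p` must be smaller than n - 1.")
  mean_pred <- mean(predicted)
  if (mean(predicted) == 0) abort("CV undefined: prediction mean is 0.")
  sse <- sum((actual - predicted)^2)
  sst <- sum((actual - mean(actual))^2)
  r2 <- 1 - sse / sst
  tibble::tibble(
    mean = mean_pred,
    sd = sd(predicted),
    min = round(min(predicted)),
    max = round(max(predicted)),
    cv = sd(predicted) / mean_pred,
    adj_r_squared = (1 - (1 - r2) * (n - 1) / (n - p - 1)) * 100,
    rmse = sqrt(sse / n),
    mae = mean(abs(actual - predicted))
  )
}

#' Taylor-diagram statistics
#'
#' Pearson correlation with the observations, sample standard deviation of
#' the predictions and the centered root-mean-square difference. The three
#' satisfy the law-of-cosines identity
#' `crmsd^2 = sd_pred^2 + sd_actual^2 - 2 sd_pred sd_actual r`.
#'
#' @inheritParams compute_metrics
#' @return A one-row tibble with `r`, `sd_pred`, `sd_actual`, `crmsd`.
#' @export
taylor_stats <- function(actual, predicted) {
  n <- length(actual)
  if (length(predicted) != n || n < 2) abort("Need equal-length vectors of length >= 2.")
  if (sd(actual) == 0 || sd(predicted) == 0) abort("Zero-variance input.")
  ca <- actual - mean(actual)
  cp <- predicted - mean(predicted)
  tibble::tibble(
    r = stats::cor(actual, predicted),
    sd_pred = sd(predicted),
    sd_actual = sd(actual),
    crmsd = sqrt(sum((cp - ca)^2) / (n - 1))
  )
}

#' Cross-model comparison report
#'
#' Assembles the full comparison table: one row for the actual test target
#' (no error metrics) followed by one row per model ordered by ascending
#' RMSE with alphabetical tie-breaks, each carrying the
#' [compute_metrics()] and [taylor_stats()] columns.
#'
#' @param predictions Named list of prediction vectors, all on the same test
#'   split (and with identical record names, when named).
#' @param actual Observed test LoS.
#' @param p Feature count for the adjusted R-squared.
#' @return A tibble of class `los_report`.
#' @export
build_report <- function(predictions, actual, p) {
  if (!length(predictions)) abort("No model predictions supplied.")
  ids <- purrr::map(predictions, names)
  ref <- ids[[1]]
  same <- purrr::every(ids, ~ identical(.x, ref))
  if (!same) abort("Prediction record ids differ: models were scored on mixed test splits.")
  if (any(lengths(predictions) != length(actual))) {
    abort("Prediction lengths differ from the actual target.")
  }
  rows <- purrr::imap_dfr(predictions, function(pred, nm) {
    dplyr::bind_cols(
      tibble::tibble(model = nm),
      compute_metrics(actual, pred, p),
      taylor_stats(actual, pred)[, c("r", "crmsd")]
    )
  })
  rows <- dplyr::arrange(rows, .data$rmse, .data$model)
  actual_row <- tibble::tibble(
    model = "Actual",
    mean = mean(actual), sd = sd(actual),
    min = round(min(actual)), max = round(max(actual)),
    cv = sd(actual) / mean(actual),
    adj_r_squared = NA_real_, rmse = NA_real_, mae = NA_real_,
    r = NA_real_, crmsd = NA_real_
  )
  out <- dplyr::bind_rows(actual_row, rows)
  class(out) <- c("los_report", class(out))
  out
}

#' @export
print.los_report <- function(x, ...) {
  cat("LoS model comparison (", nrow(x) - 1, "models )\n", sep = " ")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(col) {
    ifelse(is.na(col), "-", format(round(col, 2), trim = TRUE))
  })
  print(df, row.names = FALSE)
  invisible(x)
}

#' Taylor diagram of the comparison report
#'
#' Plots each model in (correlation azimuth, prediction-sd radius) polar
#' coordinates with the actual target on the horizontal axis.
#'
#' @param report A `los_report` from [build_report()].
#' @param ... Unused.
#' @export
plot_taylor <- function(report, ...) {
  models <- report[report$model != "Actual", ]
  sd_act <- report$sd[report$model == "Actual"]
  df <- dplyr::transmute(
    models,
    model = .data$model,
    x = .data$sd * cos(acos(pmin(pmax(.data$r, -1), 1))),
    y = .data$sd * sin(acos(pmin(pmax(.data$r, -1), 1)))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, label = .data$model)) +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::annotate("point", x = sd_act, y = 0, shape = 4, size = 3) +
    ggplot2::annotate("text", x = sd_act, y = 0, label = "Actual",
                      vjust = 1.5, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "sd x correlation (days)", y = "sd x sin(acos r) (days)",
      title = "Taylor diagram"
    ) +
    ggplot2::theme_minimal()
}
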