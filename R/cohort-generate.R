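#' Generate a synthetic CABG cohort
#'
#' Draws a cohort from a [cohort_spec()]. In realistic mode the result is a
#' full clinical table (identifier, admission/surgery/discharge dates, the two
#' LoS day-count components, 10 further continuous variables and 52
#' categorical variables) whose marginals match the packaged registry
#' calibration; missing cells are then injected completely at random at the
#' spec's per-column rates. In model-faithful mode the result is a design
#' matrix of uniform \[0, 1\] features together with a continuous `LOS` column
#' drawn from the hierarchical truncated-normal model, and the embedded
#' [ground_truth()] is returned alongside.
#'
#' The same spec and seed reproduce the identical table.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `los_cohort` with elements `table` (a tibble),
#'   `truth` (a [ground_truth()] or `NULL`) and `spec`.
#' @examples
#' coh <- generate_cohort(default_cohort_spec(seed = 7))
#' nrow(coh$table)
#' mean(coh$table$admission_to_surgery + coh$table$LOS_Surgery_to_discharge)
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) abort("`spec` must be a cohort_spec.")
  if (spec$n_patients < 1) abort("Invalid spec: `n_patients` must be >= 1.")
  with_seed(spec$seed, {
    if (spec$mode == "realistic") {
      generate_realistic(spec)
    } else {
      generate_model_faithful(spec)
    }
  })
}

# Negative binomial parametrized by mean/sd; size = mean^2 / (var - mean).
rnbinom_calibrated <- function(n, mean, sd) {
  v <- sd^2
  if (v <= mean) abort("Negative binomial needs variance > mean.")
  rnbinom(n, size = mean^2 / (v - mean), mu = mean)
}

generate_realistic <- function(spec) {
  n <- spec$n_patients
  cs <- spec$continuous_specs
  cat_specs <- spec$categorical_specs

  # LoS components: right-skewed integer day counts, capped at the calibrated
  # ranges and jointly at an overall stay of 65 days.
  a2s <- cs$admission_to_surgery
  s2d <- cs$LOS_Surgery_to_discharge
  adm <- pmin(rnbinom_calibrated(n, a2s$mean, a2s$sd), a2s$max)
  dis <- pmin(1L + rnbinom_calibrated(n, s2d$mean - 1, s2d$sd), s2d$max)
  over <- (adm + dis) > 65
  dis[over] <- 65L - adm[over]

  # Categorical variables first: the blood pressures depend on hypertension.
  cat_cols <- purrr::map(cat_specs, function(sp) {
    sp$labels[sample.int(length(sp$labels), n, replace = TRUE, prob = sp$prob)]
  })

  hyper <- cat_cols$hypertension == "Yes"
  draw_cont <- function(sp) {
    if (identical(sp$dist, "bp")) {
      mu <- ifelse(hyper, sp$mean_hyper, sp$mean_normo)
      round(rtruncnorm(n, mu, sp$sd, sp$min, sp$max))
    } else {
      rtruncnorm(n, sp$mean, sp$sd, sp$min, sp$max)
    }
  }
  cont_names <- setdiff(
    names(cs),
    c("admission_to_surgery", "LOS_Surgery_to_discharge", "BMI")
  )
  cont_cols <- purrr::map(cs[cont_names], draw_cont)
  cont_cols$patient_age <- round(cont_cols$patient_age)
  cont_cols$weight <- round(cont_cols$weight, 1)
  cont_cols$height <- round(cont_cols$height, 1)
  bmi <- round(cont_cols$weight / (cont_cols$height / 100)^2, 2)

  adm_date <- as.Date("2015-01-01") +
    sample.int(as.integer(as.Date("2020-12-31") - as.Date("2015-01-01")) + 1L,
               n, replace = TRUE) - 1L

  tab <- tibble::tibble(
    TempSNO = seq_len(n),
    date_of_admission = adm_date,
    date_of_surgery = adm_date + adm,
    date_of_discharge = adm_date + adm + dis,
    admission_to_surgery = as.integer(adm),
    LOS_Surgery_to_discharge = as.integer(dis),
    !!!cont_cols,
    BMI = bmi,
    !!!cat_cols
  )
  tab <- inject_missingness(tab, spec$missingness, seed = derive_seed(spec$seed, 97L))
  structure(list(table = tab, truth = NULL, spec = spec), class = "los_cohort")
}

default_truth <- function(n_features, n_levels, sigma, edges = c(10, 20, 30)) {
  beta <- matrix(rnorm(n_levels * n_features, 0, 1.5), n_levels, n_features,
                 dimnames = list(NULL, paste0("x", seq_len(n_features))))
  centers <- c((c(0, edges) + c(edges, edges[length(edges)] + 8)) / 2)
  beta0 <- centers[seq_len(n_levels)] - 0.5 * rowSums(beta)
  ground_truth(beta0 = beta0, beta = beta, sigma = sigma)
}

generate_model_faithful <- function(spec, edges = c(10, 20, 30), max_attempts = 1000L) {
  n <- spec$n_patients
  p <- spec$n_features
  n_levels <- length(spec$level_proportions)
  truth <- spec$truth %||% default_truth(p, n_levels, spec$sigma, edges)
  if (ncol(truth$beta) != p) abort("`truth$beta` does not match `n_features`.")
  sigma <- truth$sigma

  lev <- sample.int(n_levels, n, replace = TRUE, prob = spec$level_proportions) - 1L
  X <- matrix(runif(n * p), n, p, dimnames = list(NULL, paste0("x", seq_len(p))))
  mu <- truth$beta0[lev + 1L] + rowSums(X * truth$beta[lev + 1L, , drop = FALSE])

  # Rejection step: redraw until the LoS value falls inside the drawn level's
  # bin, so level assignments in recovery tests are exactly consistent.
  y <- rep(NA_real_, n)
  pending <- seq_len(n)
  attempts <- 0L
  while (length(pending) > 0L) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      abort(paste0("Bin-consistent LoS rejection failed for ", length(pending),
                   " records after ", max_attempts, " attempts."))
    }
    draw <- rtruncnorm(length(pending), mu[pending], sigma, lower = 0)
    ok <- assign_level(draw, edges = edges) == lev[pending]
    y[pending[ok]] <- draw[ok]
    pending <- pending[!ok]
  }

  truth$level_of_record <- lev
  tab <- tibble::tibble(tibble::as_tibble(X), LOS = y, level = lev)
  structure(list(table = tab, truth = truth, spec = spec), class = "los_cohort")
}

#' Inject missing values completely at random
#'
#' Sets each cell of the targeted columns to `NA` independently with that
#' column's rate (MCAR). Untargeted columns are returned unchanged.
#'
#' @param table A cohort tibble.
#' @param rates Named numeric vector of per-column missingness rates.
#' @param seed Integer seed.
#' @return The table with missing cells injected.
#' @export
inject_missingness <- function(table, rates, seed = 1L) {
  if (length(rates) == 0L) return(table)
  unknown <- setdiff(names(rates), names(table))
  if (length(unknown)) {
    abort(paste0("Unknown column(s) in `rates`: ", paste(unknown, collapse = ", ")))
  }
  with_seed(seed, {
    for (nm in names(rates)) {
      if (rates[[nm]] <= 0) next
      hit <- runif(nrow(table)) < rates[[nm]]
      table[[nm]][hit] <- NA
    }
  })
  table
}

#' @export
print.los_cohort <- function(x, ...) {
  cat("<los_cohort>", x$spec$mode, "mode:", nrow(x$table), "records,",
      ncol(x$table), "columns\n")
  if (!is.null(x$truth)) {
    cat("  embedded ground truth:", length(x$truth$beta0), "levels x",
        ncol(x$truth$beta), "features, sigma =", x$truth$sigma, "\n")
  }
  invisible(x)
}

#' Write and read a cohort directory
#'
#' `write_cohort()` serializes a cohort as `cohort.csv` plus a JSON column
#' dictionary (`columns.json`: name, type, labels) and, when present,
#' `truth.json`. `read_cohort()` restores the table with column types taken
#' from the dictionary.
#'
#' @param cohort A `los_cohort`.
#' @param dir Directory to write into (created if absent).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` returns a
#'   list with `table` and `truth`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- cohort$table
  utils::write.csv(tab, file.path(dir, "cohort.csv"), row.names = FALSE, na = "")
  dict <- purrr::imap(tab, function(col, nm) {
    list(
      name = nm,
      type = if (inherits(col, "Date")) "date"
             else if (is.character(col)) "categorical" else "continuous",
      labels = if (is.character(col)) sort(unique(col[!is.na(col)])) else NULL
    )
  })
  jsonlite::write_json(unname(dict), file.path(dir, "columns.json"),
                       auto_unbox = TRUE, null = "null")
  if (!is.null(cohort$truth)) {
    tr <- cohort$truth
    jsonlite::write_json(
      list(beta0 = tr$beta0, beta = tr$beta, sigma = tr$sigma,
           level_of_record = tr$level_of_record),
      file.path(dir, "truth.json"), digits = NA, matrix = "rowmajor"
    )
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  dict <- jsonlite::read_json(file.path(dir, "columns.json"))
  types <- purrr::map_chr(dict, "type")
  names(types) <- purrr::map_chr(dict, "name")
  col_classes <- c(date = "Date", categorical = "character", continuous = "numeric")
  tab <- utils::read.csv(file.path(dir, "cohort.csv"), check.names = FALSE,
                         colClasses = unname(col_classes[types]), na.strings = "")
  tab <- tibble::as_tibble(tab)
  truth <- NULL
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf)) {
    raw <- jsonlite::read_json(tf, simplifyVector = TRUE)
    truth <- ground_truth(raw$beta0, raw$beta, raw$sigma, raw$level_of_record)
  }
  list(table = tab, truth = truth)
}
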