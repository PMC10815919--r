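#' Reference-based imputation of BMI
#'
#' Fills missing `BMI` cells from `weight` (kg) and `height` (cm) as
#' `weight / (height / 100)^2`. Present BMI values are never altered. Records
#' where BMI, weight and height are all unavailable keep a missing BMI and are
#' removed later by [drop_sparse_rows()].
#'
#' @param table A cohort tibble with `BMI`, `weight` and `height` columns.
#' @return The table with BMI imputed.
#' @examples
#' tb <- tibble::tibble(BMI = c(NA, 30), weight = c(71.87, 80), height = c(163.6, 180))
#' impute_bmi(tb)$BMI
#' @export
impute_bmi <- function(table) {
  need <- c("BMI", "weight", "height")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols)) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  fill <- is.na(table$BMI) & !is.na(table$weight) & !is.na(table$height)
  table$BMI[fill] <- table$weight[fill] / (table$height[fill] / 100)^2
  table
}

#' Conditional-mean imputation of blood pressures
#'
#' Fills missing `BPsystolic` and `diastolic` values with the mean observed in
#' patients sharing the record's `hypertension` label. Systolic means default
#' to the published reference values (124 mmHg for hypertensive, 117 mmHg for
#' normotensive patients); when `NULL` they are recomputed from the non-missing
#' rows in `train` (all rows when `train` is `NULL`). Diastolic means are
#' always computed from the data, stratified the same way. Records whose
#' hypertension label is itself missing keep their missing value and are
#' removed later by [drop_sparse_rows()].
#'
#' @param table A cohort tibble with `hypertension`, `BPsystolic` and
#'   `diastolic` columns.
#' @param hyper_mean,normo_mean Systolic imputation means in mmHg, or `NULL`
#'   to estimate them from `train` rows.
#' @param train Optional integer row indices defining the training rows used
#'   for estimating imputation means (leakage control).
#' @return The table with blood pressures imputed.
#' @export
impute_bp <- function(table, hyper_mean = 124, normo_mean = 117, train = NULL) {
  need <- c("hypertension", "BPsystolic", "diastolic")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols)) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  ref_rows <- train %||% seq_len(nrow(table))
  strat_mean <- function(col, label) {
    idx <- intersect(ref_rows, which(table$hypertension == label & !is.na(col)))
    mean(col[idx])
  }
  fill_col <- function(col, m_yes, m_no) {
    miss <- is.na(col) & !is.na(table$hypertension)
    col[miss] <- ifelse(table$hypertension[miss] == "Yes", m_yes, m_no)
    col
  }
  hm <- hyper_mean %||% strat_mean(table$BPsystolic, "Yes")
  nm <- normo_mean %||% strat_mean(table$BPsystolic, "No")
  table$BPsystolic <- fill_col(table$BPsystolic, hm, nm)
  table$diastolic <- fill_col(
    table$diastolic,
    strat_mean(table$diastolic, "Yes"),
    strat_mean(table$diastolic, "No")
  )
  table
}

#' Remove the residual incomplete records
#'
#' Drops every row still containing a missing value after the imputation
#' steps (in the packaged cohort these are rows missing
#' `pulmonary_artery_done`, `last_wbc_count` or `pulmonary_insufficiency`,
#' plus any record whose imputation references were unavailable). Refuses to
#' proceed when removal would exceed the 5% completeness benchmark.
#'
#' @param table A cohort tibble after imputation.
#' @param threshold Maximum tolerated fraction of dropped rows.
#' @return The table restricted to complete rows.
#' @export
drop_sparse_rows <- function(table, threshold = 0.05) {
  keep <- complete.cases(table)
  frac <- mean(!keep)
  if (frac > threshold) {
    abort(sprintf(
      "Row removal would discard %.1f%% of records, above the %.0f%% benchmark.",
      100 * frac, 100 * threshold
    ))
  }
  table[keep, , drop = FALSE]
}

#' Construct the length-of-stay target
#'
#' Appends `LOS = admission_to_surgery + LOS_Surgery_to_discharge` and removes
#' the identifier, the three calendar-date columns, `weight`, `height` and the
#' two component columns, leaving the modelling table (61 columns on the
#' packaged 68-variable cohort, including the target).
#'
#' @param table A cohort tibble with both component columns.
#' @return The modelling table with an `LOS` column.
#' @export
build_target <- function(table) {
  comp <- c("admission_to_surgery", "LOS_Surgery_to_discharge")
  missing_cols <- setdiff(comp, names(table))
  if (length(missing_cols)) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  a <- table[[comp[1]]]
  b <- table[[comp[2]]]
  if (any(a < 0, na.rm = TRUE) || any(b < 0, na.rm = TRUE)) {
    abort("LoS components must be nonnegative.")
  }
  drop_cols <- intersect(
    c("TempSNO", "date_of_admission", "date_of_surgery", "date_of_discharge",
      "weight", "height", comp),
    names(table)
  )
  table$LOS <- a + b
  table[, setdiff(names(table), drop_cols), drop = FALSE]
}

#' Label-encode the categorical columns
#'
#' Maps every categorical (character or factor) column to integer codes
#' starting at 0, assigned by alphabetically sorted labels so the encoding is
#' deterministic and locale-independent. Continuous columns pass through.
#' When `encoders` is supplied the stored maps are applied instead and an
#' unseen label raises an error naming the label and column.
#'
#' @param table A complete (no missing values) modelling tibble.
#' @param target Name of the target column, kept aside unencoded.
#' @param encoders Optional encoder list from a previous `encode()` call.
#' @return A list of class `los_matrix`: `values` (all-numeric tibble),
#'   `columns` (per-column metadata: name, kind, encoding map), `target`
#'   (numeric vector or `NULL`).
#' @export
encode <- function(table, target = "LOS", encoders = NULL) {
  if (anyNA(table)) abort("`table` must not contain missing values; impute first.")
  y <- NULL
  if (!is.null(target) && target %in% names(table)) {
    y <- as.numeric(table[[target]])
    table <- table[, setdiff(names(table), target), drop = FALSE]
  }
  is_cat <- vapply(table, function(col) is.character(col) || is.factor(col), logical(1))
  if (is.null(encoders)) {
    encoders <- purrr::map(table[is_cat], function(col) {
      labs <- sort(unique(as.character(col)), method = "radix")
      setNames(seq_along(labs) - 1L, labs)
    })
  }
  values <- purrr::imap(table, function(col, nm) {
    if (!is_cat[[nm]]) return(as.numeric(col))
    map <- encoders[[nm]]
    if (is.null(map)) abort(paste0("No encoder stored for column `", nm, "`."))
    col <- as.character(col)
    unseen <- setdiff(unique(col), names(map))
    if (length(unseen)) {
      abort(paste0("Unseen label(s) in column `", nm, "`: ",
                   paste(unseen, collapse = ", ")))
    }
    as.numeric(map[col])
  })
  columns <- tibble::tibble(
    name = names(table),
    kind = ifelse(is_cat, "categorical", "continuous"),
    encoding = purrr::map(names(table), ~ encoders[[.x]])
  )
  structure(
    list(values = tibble::as_tibble(values), columns = columns, target = y),
    class = "los_matrix"
  )
}

#' @rdname encode
#' @param matrix A `los_matrix`.
#' @export
decode <- function(matrix) {
  stopifnot(inherits(matrix, "los_matrix"))
  out <- purrr::pmap(matrix$columns, function(name, kind, encoding) {
    col <- matrix$values[[name]]
    if (kind == "continuous") return(col)
    names(encoding)[match(col, encoding)]
  })
  names(out) <- matrix$columns$name
  tibble::as_tibble(out)
}

#' @export
print.los_matrix <- function(x, ...) {
  cat("<los_matrix>", nrow(x$values), "x", ncol(x$values), "(",
      sum(x$columns$kind == "continuous"), "continuous,",
      sum(x$columns$kind == "categorical"), "encoded categorical )\n")
  invisible(x)
}

#' Seeded train/test partition
#'
#' Uniformly random disjoint partition of the rows of an encoded matrix (or
#' any object with rows) into a training fraction and its complement.
#'
#' @param matrix A `los_matrix`, data frame, or integer row count.
#' @param fraction Training fraction; the training size is
#'   `round(fraction * n)`.
#' @param seed Integer seed.
#' @return A list of class `los_split` with sorted integer `train` and `test`
#'   index vectors and the seed.
#' @export
split_matrix <- function(matrix, fraction = 0.8, seed = 1L) {
  n <- if (inherits(matrix, "los_matrix")) nrow(matrix$values)
       else if (is.data.frame(matrix)) nrow(matrix)
       else as.integer(matrix)
  if (n < 5) abort("Need at least 5 rows to split.")
  n_train <- round(fraction * n)
  train <- with_seed(seed, sort(sample.int(n, n_train)))
  structure(
    list(train = train, test = setdiff(seq_len(n), train), seed = as.integer(seed)),
    class = "los_split"
  )
}

#' Min-max scaling fitted on training rows
#'
#' `scale_fit()` learns per-column minima and maxima from the training rows
#' only; `scale_apply()` maps every value through
#' `(x - min) / (max - min)`. Columns constant on the training rows map to 0,
#' and test values may fall outside \[0, 1\] (no clipping).
#'
#' @param matrix A `los_matrix`.
#' @param train Integer training row indices.
#' @param columns `"all"` to scale every model column (the default, so
#'   coefficient magnitudes are comparable across mixed types) or
#'   `"continuous"` to scale continuous columns only.
#' @return `scale_fit()` returns a `los_scaler` tibble (`name`, `min`, `max`);
#'   `scale_apply()` returns the scaled `los_matrix`.
#' @export
scale_fit <- function(matrix, train, columns = c("all", "continuous")) {
  stopifnot(inherits(matrix, "los_matrix"))
  columns <- match.arg(columns)
  nms <- if (columns == "all") matrix$columns$name
         else matrix$columns$name[matrix$columns$kind == "continuous"]
  vals <- matrix$values[train, nms, drop = FALSE]
  structure(
    tibble::tibble(
      name = nms,
      min = purrr::map_dbl(vals, min),
      max = purrr::map_dbl(vals, max)
    ),
    class = c("los_scaler", "tbl_df", "tbl", "data.frame")
  )
}

#' @rdname scale_fit
#' @param scaler A `los_scaler` from [scale_fit()].
#' @export
scale_apply <- function(matrix, scaler) {
  stopifnot(inherits(matrix, "los_matrix"), inherits(scaler, "los_scaler"))
  for (i in seq_len(nrow(scaler))) {
    nm <- scaler$name[i]
    rng <- scaler$max[i] - scaler$min[i]
    x <- matrix$values[[nm]]
    matrix$values[[nm]] <- if (rng == 0) rep(0, length(x)) else (x - scaler$min[i]) / rng
  }
  matrix
}

#' Run the full preprocessing pipeline on a raw cohort table
#'
#' Applies, in order: BMI imputation, removal of residual incomplete rows,
#' the seeded train/test split, blood-pressure imputation with means taken
#' from training rows only, target construction, label encoding and min-max
#' scaling fitted on the training rows. No statistic of any test row
#' influences the fitted scaler, encoders or imputation means.
#'
#' @param table A raw cohort tibble (realistic-mode [generate_cohort()]
#'   output).
#' @param seed Integer seed for the split.
#' @param fraction Training fraction.
#' @param bp_means Length-2 numeric `c(hyper, normo)` systolic imputation
#'   means, or `NULL` to estimate them from the training rows.
#' @param scale_columns Passed to [scale_fit()].
#' @return A list of class `los_prepared`: `matrix` (scaled `los_matrix`),
#'   `split` (`los_split`), `scaler`, and `features` (model column names).
#' @export
preprocess_cohort <- function(table, seed = 1L, fraction = 0.8,
                              bp_means = NULL, scale_columns = "all") {
  tab <- impute_bmi(table)
  # The three named audit columns are the only ones that may stay missing
  # after reference imputation succeeds; rows failing imputation are caught
  # here too because their BMI/BP cells are still missing.
  tab_bp_tmp <- impute_bp(tab, hyper_mean = 0, normo_mean = 0)  # probe fill
  droppable <- !complete.cases(tab_bp_tmp)
  frac <- mean(droppable)
  if (frac > 0.05) {
    abort(sprintf("Row removal would discard %.1f%% of records, above the 5%% benchmark.",
                  100 * frac))
  }
  tab <- tab[!droppable, , drop = FALSE]

  split <- split_matrix(nrow(tab), fraction = fraction, seed = seed)
  tab <- impute_bp(
    tab,
    hyper_mean = if (is.null(bp_means)) NULL else bp_means[1],
    normo_mean = if (is.null(bp_means)) NULL else bp_means[2],
    train = split$train
  )
  tab <- drop_sparse_rows(tab)
  tab <- build_target(tab)
  mat <- encode(tab, target = "LOS")
  scaler <- scale_fit(mat, split$train, columns = scale_columns)
  mat <- scale_apply(mat, scaler)
  structure(
    list(matrix = mat, split = split, scaler = scaler,
         features = mat$columns$name),
    class = "los_prepared"
  )
}
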