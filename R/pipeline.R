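#' Pipeline run configuration
#'
#' Collects every setting of the end-to-end workflow (simulate ->
#' preprocess -> select -> fit -> evaluate) in one serializable object. Each
#' stage's seed is derived deterministically from the master seed, so a
#' config reproduces a run exactly. The config round-trips through YAML
#' unchanged ([write_config()] / [read_config()]).
#'
#' @param out_dir Run directory for all artifacts.
#' @param seed Master integer seed.
#' @param n_patients Cohort size.
#' @param mode Cohort mode, `"realistic"` or `"model_faithful"`.
#' @param split_fraction Training fraction of the outer split.
#' @param pfi_k Permutation repetitions per feature.
#' @param use_packaged_features Use the packaged 44-variable reference list
#'   instead of running the permutation screen.
#' @param chains,draws,tune MCMC configuration.
#' @param level_edges Interior LoS bin edges (days).
#' @param level_mode Test-time level assignment, `"oracle"` or `"marginal"`.
#' @param models Character vector drawn from `"sbm"`, `"hbm"` and
#'   [baseline_ids()].
#' @return A list of class `los_config`.
#' @export
los_config <- function(out_dir = tempfile("los_run_"), seed = 1L,
                       n_patients = 5363L, mode = "realistic",
                       split_fraction = 0.8, pfi_k = 10L,
                       use_packaged_features = FALSE,
                       chains = 4L, draws = 3000L, tune = 1000L,
                       level_edges = c(10, 20, 30),
                       level_mode = "oracle",
                       models = c("sbm", "hbm", baseline_ids())) {
  structure(
    list(out_dir = out_dir, seed = as.integer(seed),
         n_patients = as.integer(n_patients), mode = mode,
         split_fraction = split_fraction, pfi_k = as.integer(pfi_k),
         use_packaged_features = use_packaged_features,
         chains = as.integer(chains), draws = as.integer(draws),
         tune = as.integer(tune), level_edges = level_edges,
         level_mode = level_mode, models = models),
    class = "los_config"
  )
}

#' @rdname los_config
#' @param config A `los_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname los_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(los_config, raw)
}

#' Run the full LoS analysis pipeline
#'
#' Executes every stage in order on a synthetic cohort: generation,
#' preprocessing (imputation, split, encoding, leakage-free scaling),
#' permutation feature selection on the training rows, Bayesian and baseline
#' model fits on the selected features, and the comparison report. All
#' intermediate artifacts (cohort, importance report, coefficient summaries,
#' predictions, metrics, run log) are written under `config$out_dir`;
#' re-running the same config reproduces every numeric output.
#'
#' @param config A [los_config()].
#' @return A list with `report` (a `los_report`), `importance`, `selected`,
#'   `fits` (posterior objects), `prepared` and `out_dir`, invisibly
#'   returned components written to disk.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "los_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(
    paste0("bayeslos pipeline run ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("R ", getRversion(), "; bayeslos ",
           as.character(utils::packageVersion("bayeslos"))),
    paste0("master seed ", config$seed)
  )
  stage <- function(nm, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Pipeline stage `", nm, "` failed: ", conditionMessage(e)))
    })
  }

  # -- simulate ---------------------------------------------------------
  spec <- if (config$mode == "realistic") {
    sp <- default_cohort_spec(seed = derive_seed(config$seed, 1L))
    sp$n_patients <- config$n_patients
    sp
  } else {
    model_faithful_spec(n_patients = config$n_patients,
                        seed = derive_seed(config$seed, 1L))
  }
  cohort <- stage("simulate", generate_cohort(spec))
  write_cohort(cohort, file.path(config$out_dir, "cohort"))
  log_lines <- c(log_lines, paste0("simulate: ", nrow(cohort$table), " records, seed ",
                                   spec$seed))

  # -- preprocess -------------------------------------------------------
  if (config$mode == "realistic") {
    prep <- stage("preprocess", preprocess_cohort(
      cohort$table, seed = derive_seed(config$seed, 2L),
      fraction = config$split_fraction
    ))
  } else {
    # Model-faithful cohorts are already an encoded, scaled design.
    prep <- stage("preprocess", {
      mat <- encode(cohort$table[, setdiff(names(cohort$table), "level")],
                    target = "LOS")
      split <- split_matrix(mat, fraction = config$split_fraction,
                            seed = derive_seed(config$seed, 2L))
      list(matrix = mat, split = split, scaler = NULL,
           features = mat$columns$name)
    })
  }
  log_lines <- c(log_lines, paste0(
    "preprocess: ", length(prep$split$train), " train / ",
    length(prep$split$test), " test rows, ",
    length(prep$features), " features, split seed ", prep$split$seed))

  X <- as.matrix(prep$matrix$values)
  y <- prep$matrix$target
  tr <- prep$split$train
  te <- prep$split$test

  # -- select -----------------------------------------------------------
  sel_seed <- derive_seed(config$seed, 3L)
  if (config$use_packaged_features) {
    selected <- intersect(los_selected_features(), colnames(X))
    importance <- NULL
    log_lines <- c(log_lines, paste0("select: packaged reference list, ",
                                     length(selected), " features"))
  } else {
    inner <- stage("select", inner_split(tr, config$split_fraction, seed = sel_seed))
    base <- stage("select", fit_base_model(X[inner$fit, , drop = FALSE],
                                           y[inner$fit], seed = sel_seed))
    importance <- stage("select", permutation_importance(
      base, X[inner$validate, , drop = FALSE], y[inner$validate],
      K = config$pfi_k, seed = sel_seed))
    utils::write.csv(importance, file.path(config$out_dir, "importance.csv"),
                     row.names = FALSE)
    selected <- select_features(importance)
    if (!length(selected)) selected <- colnames(X)  # degenerate no-signal cohort
    log_lines <- c(log_lines, paste0("select: PFI K=", config$pfi_k, ", seed ",
                                     sel_seed, ", ", length(selected),
                                     " features selected"))
  }
  Xs <- X[, selected, drop = FALSE]

  # -- fit --------------------------------------------------------------
  fit_seed <- derive_seed(config$seed, 4L)
  predictions <- list()
  fits <- list()
  for (kind in intersect(config$models, c("sbm", "hbm"))) {
    model <- stage(kind, los_model(Xs[tr, , drop = FALSE], y[tr], kind = kind,
                                   edges = config$level_edges))
    post <- stage(kind, sample_posterior(model, chains = config$chains,
                                         draws = config$draws,
                                         tune = config$tune, seed = fit_seed))
    pr <- stage(kind, predict(post, Xs[te, , drop = FALSE],
                              level_mode = config$level_mode, y_test = y[te]))
    predictions[[toupper(kind)]] <- pr$.pred
    fits[[kind]] <- post
    utils::write.csv(summarize_coefficients(post),
                     file.path(config$out_dir, paste0(kind, "_coefficients.csv")),
                     row.names = FALSE)
    r <- rhat(post)
    log_lines <- c(log_lines, sprintf(
      "%s: %d chains x %d draws (tune %d), seed %d, max rhat %.3f, divergences %d",
      kind, config$chains, config$draws, config$tune, fit_seed,
      max(r$rhat), post$divergence_count))
  }
  base_ids <- intersect(config$models, baseline_ids())
  if (length(base_ids)) {
    base_preds <- stage("baselines", run_baselines(
      Xs[tr, , drop = FALSE], y[tr], Xs[te, , drop = FALSE],
      seed = derive_seed(config$seed, 5L)))
    predictions <- c(predictions, base_preds[base_ids])
    log_lines <- c(log_lines, paste0("baselines: ", paste(base_ids, collapse = ", ")))
  }

  # -- evaluate ---------------------------------------------------------
  report <- stage("evaluate", build_report(predictions, y[te], p = ncol(Xs)))
  utils::write.csv(report, file.path(config$out_dir, "metrics.csv"),
                   row.names = FALSE)
  preds_df <- tibble::tibble(record = te, actual = y[te], !!!predictions)
  utils::write.csv(preds_df, file.path(config$out_dir, "predictions.csv"),
                   row.names = FALSE)
  write_config(config, file.path(config$out_dir, "config.yaml"))
  writeLines(log_lines, file.path(config$out_dir, "run.log"))

  invisible(list(report = report, importance = importance, selected = selected,
                 fits = fits, prepared = prep, out_dir = config$out_dir))
}
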