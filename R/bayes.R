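#' Assign LoS levels
#'
#' Bins a length of stay (days) into the four hierarchy levels using
#' half-open intervals: \[0, 10) -> 0, \[10, 20) -> 1, \[20, 30) -> 2 and
#' \[30, Inf) -> 3 for the default edges.
#'
#' @param los Numeric vector of lengths of stay in days (`>= 0`).
#' @param edges Increasing interior bin edges (default `c(10, 20, 30)`).
#' @return Integer vector of 0-based level indices.
#' @examples
#' assign_level(c(5, 10, 30))
#' @export
assign_level <- function(los, edges = c(10, 20, 30)) {
  if (any(los < 0, na.rm = TRUE)) abort("LoS must be nonnegative.")
  findInterval(los, edges)
}

#' Prior specification for the Bayesian LoS models
#'
#' Coefficients and intercepts are drawn `Normal(mu, sd)` where the means
#' have `Normal(mu_loc, mu_scale)` hyperpriors and the standard deviations
#' `Half-Normal(sigma_scale)` hyperpriors; the shared noise scale has a
#' `Half-Normal(noise_scale)` prior. All scales are in days (the design is
#' scaled to \[0, 1\], the target is not). The `fixed_*` arguments pin the
#' corresponding quantity instead of sampling it, which turns the hierarchy
#' into a fixed-prior regression (used, e.g., for conjugate checks).
#'
#' @param mu_loc,mu_scale Hyperprior location and scale of the coefficient
#'   means (days).
#' @param sigma_scale Half-normal scale of the coefficient standard
#'   deviations (days).
#' @param noise_scale Half-normal scale of the observation noise (days).
#' @param fixed_mu,fixed_sigma Optional fixed coefficient prior mean and sd.
#' @param fixed_noise Optional fixed noise scale.
#' @return A list of class `los_prior`.
#' @export
prior_spec <- function(mu_loc = 0, mu_scale = 10, sigma_scale = 10,
                       noise_scale = 5, fixed_mu = NULL, fixed_sigma = NULL,
                       fixed_noise = NULL) {
  if (mu_scale <= 0 || sigma_scale <= 0 || noise_scale <= 0) {
    abort("All prior scales must be positive.")
  }
  if (!is.null(fixed_sigma) && fixed_sigma <= 0) abort("`fixed_sigma` must be positive.")
  if (!is.null(fixed_noise) && fixed_noise <= 0) abort("`fixed_noise` must be positive.")
  structure(
    list(mu_loc = mu_loc, mu_scale = mu_scale, sigma_scale = sigma_scale,
         noise_scale = noise_scale, fixed_mu = fixed_mu,
         fixed_sigma = fixed_sigma, fixed_noise = fixed_noise),
    class = "los_prior"
  )
}

#' Build a simple or hierarchical Bayesian LoS regression model
#'
#' Assembles the model: a truncated-at-zero normal likelihood
#' `y_i ~ TruncNormal(beta0[l_i] + x_i' beta[l_i, ], sigma; 0, Inf)` with one
#' intercept and coefficient vector per LoS level (`kind = "hbm"`), partially
#' pooled through shared hyperpriors, or the single-level special case
#' (`kind = "sbm"`). Level indices default to [assign_level()] of the
#' observed target.
#'
#' @param X Design matrix or tibble (numeric, finite; scaled to \[0, 1\]).
#' @param y Observed LoS vector (days, `>= 0`).
#' @param kind `"hbm"` or `"sbm"`.
#' @param level Optional 0-based level index per record (HBM only).
#' @param edges Interior LoS bin edges.
#' @param priors A [prior_spec()].
#' @return A list of class `los_model`.
#' @examples
#' X <- matrix(runif(40), 20, 2, dimnames = list(NULL, c("a", "b")))
#' y <- runif(20, 2, 12)
#' m <- los_model(X, y, kind = "hbm")
#' n_parameters(m)
#' @export
los_model <- function(X, y, kind = c("hbm", "sbm"), level = NULL,
                      edges = c(10, 20, 30), priors = prior_spec()) {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (!all(is.finite(X))) abort("Design matrix contains non-finite values.")
  if (length(y) != nrow(X)) abort("`y` and `X` disagree in length.")
  if (any(y < 0)) abort("LoS must be nonnegative.")
  n_levels <- if (kind == "sbm") 1L else length(edges) + 1L
  if (kind == "sbm") {
    level <- rep(0L, length(y))
  } else if (is.null(level)) {
    level <- assign_level(y, edges)
  }
  level <- as.integer(level)
  if (any(level < 0L) || any(level >= n_levels)) {
    abort(sprintf("Level indices must lie in 0..%d.", n_levels - 1L))
  }
  structure(
    list(X = X, y = as.numeric(y), level = level, kind = kind,
         edges = edges, n_levels = n_levels, priors = priors,
         features = colnames(X)),
    class = "los_model"
  )
}

#' Parameter-node counts of a model
#'
#' @param model A [los_model()].
#' @return A list with `intercepts`, `coefficients` and `noise` counts.
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "los_model"))
  list(
    intercepts = model$n_levels,
    coefficients = model$n_levels * ncol(model$X),
    noise = 1L
  )
}

#' @export
print.los_model <- function(x, ...) {
  np <- n_parameters(x)
  cat("<los_model>", toupper(x$kind), "on", length(x$y), "records,",
      ncol(x$X), "features,", x$n_levels, "level(s)\n")
  cat("  parameter nodes:", np$intercepts, "intercepts,",
      np$coefficients, "coefficients, 1 noise scale\n")
  invisible(x)
}

param_names <- function(model) {
  L <- model$n_levels
  feats <- model$features
  c(
    sprintf("beta0[%d]", seq_len(L) - 1L),
    as.vector(t(outer(seq_len(L) - 1L, feats,
                      function(l, f) sprintf("beta[%d,%s]", l, f)))),
    "sigma", "mu_beta0", "sigma_beta0", "mu_beta", "sigma_beta"
  )
}

#' Draw from the posterior by MCMC
#'
#' Runs the compiled blocked Gibbs sampler. The truncated-normal likelihood
#' is handled by augmenting each observation with its latent rejected draws
#' (Geometric(Phi(mu_i/sigma)) values from the negative half-line), after
#' which every conditional is exact: multivariate-normal draws for each
#' level's intercept-and-coefficient block, conjugate normal updates for the
#' hyper-means and slice updates for the scales. Chains are initialized at
#' data-driven values with seeded per-chain jitter and run sequentially;
#' identical seeds reproduce identical draws.
#'
#' @param model A [los_model()].
#' @param chains Number of chains (`>= 2`).
#' @param draws Kept draws per chain after warm-up.
#' @param tune Warm-up iterations discarded per chain.
#' @param seed Integer master seed.
#' @return An object of class `los_posterior`: per-chain draw matrices with
#'   named columns, the sampler configuration, the mean number of latent
#'   rejections per sweep (`aug_rate`, a measure of how strongly the
#'   truncation bites) and the divergence count (identically 0: a Gibbs
#'   sampler with exact conditionals has no divergent trajectories).
#' @export
sample_posterior <- function(model, chains = 4, draws = 3000, tune = 1000,
                             seed = 1L) {
  stopifnot(inherits(model, "los_model"))
  if (chains < 2) abort("Need at least 2 chains for convergence diagnostics.")
  if (draws < 1) abort("`draws` must be at least 1.")
  pr <- model$priors
  check <- los_loglik(model, beta0 = rep(mean(model$y), model$n_levels),
                      beta = matrix(0, model$n_levels, ncol(model$X)),
                      sigma = max(sd(model$y), 1e-3))
  if (!is.finite(check)) abort("Non-finite log-density at initialization.")

  L <- model$n_levels
  P <- ncol(model$X)
  lev_means <- vapply(seq_len(L) - 1L, function(l) {
    yl <- model$y[model$level == l]
    if (length(yl)) mean(yl) else mean(model$y)
  }, numeric(1))
  sigma0 <- max(sd(model$y - lev_means[model$level + 1L]), 0.1)

  chain_draws <- purrr::map(seq_len(chains), function(k) {
    with_seed(derive_seed(seed, k), {
      init_B <- cbind(lev_means + rnorm(L, 0, 0.1 * sigma0 + 0.01),
                      matrix(rnorm(L * P, 0, 0.1), L, P))
      res <- .gibbs_chain(
        model$X, model$y, model$level, L, unclass(pr),
        as.integer(draws), as.integer(tune),
        init_B, sigma0 * exp(rnorm(1, 0, 0.1)),
        pr$fixed_mu %||% mean(lev_means), pr$fixed_sigma %||% 1,
        pr$fixed_mu %||% 0, pr$fixed_sigma %||% 1
      )
      colnames(res$draws) <- param_names(model)
      res
    })
  })
  structure(
    list(
      draws = purrr::map(chain_draws, "draws"),
      aug_rate = purrr::map_dbl(chain_draws, "augmented"),
      chains = as.integer(chains), n_draws = as.integer(draws),
      tune = as.integer(tune), divergence_count = 0L, seed = as.integer(seed),
      model = model
    ),
    class = "los_posterior"
  )
}

#' @export
print.los_posterior <- function(x, ...) {
  cat("<los_posterior>", toupper(x$model$kind), ":", x$chains, "chains x",
      x$n_draws, "draws (", x$tune, "warm-up ),",
      length(param_names(x$model)), "parameters\n")
  cat("  divergences:", x$divergence_count,
      "| mean latent rejections per sweep:",
      format(mean(x$aug_rate), digits = 3), "\n")
  invisible(x)
}

as_draws_matrix <- function(samples) do.call(rbind, samples$draws)

#' Split-chain Gelman--Rubin diagnostic
#'
#' Computes the split-chain potential scale reduction factor for every
#' parameter. Each chain is halved, the between- and within-half variances
#' are combined, and parameters whose chains are all constant return exactly
#' 1. Parameters above 1.05 are flagged.
#'
#' @param samples A `los_posterior` (or a list of chain draw matrices).
#' @return A tibble with `parameter`, `rhat` and `flagged`.
#' @export
rhat <- function(samples) {
  chains <- if (inherits(samples, "los_posterior")) samples$draws else samples
  if (length(chains) < 2) abort("Need at least 2 chains for the diagnostic.")
  halves <- purrr::list_flatten(purrr::map(chains, function(m) {
    n <- nrow(m)
    h <- n %/% 2
    list(m[seq_len(h), , drop = FALSE], m[(h + 1):(2 * h), , drop = FALSE])
  }))
  n <- nrow(halves[[1]])
  np <- ncol(halves[[1]])
  means <- matrix(vapply(halves, colMeans, numeric(np)), nrow = np)
  vars <- matrix(vapply(halves, function(m) apply(m, 2, var), numeric(np)),
                 nrow = np)
  W <- rowMeans(vars)
  B <- n * apply(means, 1, var)
  r <- sqrt(((n - 1) / n * W + B / n) / W)
  r[W == 0 & B == 0] <- 1
  r[W == 0 & B > 0] <- Inf
  tibble::tibble(
    parameter = colnames(halves[[1]]),
    rhat = unname(r),
    flagged = unname(r) > 1.05
  )
}

# Mean of a normal truncated below at 0: mu + sigma * phi(z) / Phi(z).
truncnorm_mean <- function(mu, sigma) {
  z <- mu / sigma
  mu + sigma * exp(dnorm(z, log = TRUE) - pnorm(z, log.p = TRUE))
}

#' Posterior predictions for test records
#'
#' Produces per-record posterior predictive means and central credible
#' intervals. In `"oracle"` mode each test record uses the parameters of the
#' level implied by its *observed* LoS (this replicates the reference
#' evaluation protocol and leaks the outcome; see the vignette). In
#' `"marginal"` mode the predictive distribution is the mixture over levels
#' weighted by the training-set level frequencies, which is leakage-free.
#'
#' @param object A `los_posterior`.
#' @param X_test Test design matrix/tibble (same columns as the training
#'   design).
#' @param level_mode `"oracle"` or `"marginal"`.
#' @param y_test Observed test LoS; required in oracle mode.
#' @param interval Central credible mass for the bounds.
#' @param ... Unused.
#' @return A tibble with `.pred`, `.lower`, `.upper` (days, all `>= 0`) and
#'   the `level_mode` attribute.
#' @export
predict.los_posterior <- function(object, X_test, level_mode = c("oracle", "marginal"),
                                  y_test = NULL, interval = 0.9, ...) {
  level_mode <- match.arg(level_mode)
  model <- object$model
  X_test <- as.matrix(X_test)[, model$features, drop = FALSE]
  m <- as_draws_matrix(object)
  L <- model$n_levels
  n <- nrow(X_test)
  b0 <- m[, sprintf("beta0[%d]", seq_len(L) - 1L), drop = FALSE]
  betas <- purrr::map(seq_len(L) - 1L, function(l) {
    m[, sprintf("beta[%d,%s]", l, model$features), drop = FALSE]
  })
  sig <- m[, "sigma"]

  # draws x records matrix of predictive means per level
  level_pred <- function(l) {
    mu <- tcrossprod(betas[[l + 1L]], X_test) + b0[, l + 1L]
    truncnorm_mean(mu, sig)
  }
  alpha <- (1 - interval) / 2
  if (level_mode == "oracle") {
    if (is.null(y_test)) abort("Oracle mode requires `y_test` to derive levels.")
    lev <- if (L == 1L) rep(0L, n) else assign_level(y_test, model$edges)
    preds <- matrix(NA_real_, nrow(m), n)
    for (l in unique(lev)) {
      cols <- which(lev == l)
      preds[, cols] <- level_pred(l)[, cols, drop = FALSE]
    }
  } else {
    w <- tabulate(model$level + 1L, nbins = L) / length(model$level)
    preds <- matrix(0, nrow(m), n)
    for (l in seq_len(L) - 1L) {
      if (w[l + 1L] > 0) preds <- preds + w[l + 1L] * level_pred(l)
    }
  }
  qs <- apply(preds, 2, quantile, probs = c(alpha, 1 - alpha), names = FALSE)
  out <- tibble::tibble(
    .pred = pmax(colMeans(preds), 0),
    .lower = pmax(qs[1, ], 0),
    .upper = qs[2, ]
  )
  attr(out, "level_mode") <- level_mode
  out
}

#' Truncated-normal log-likelihood of the model
#'
#' Evaluates the joint log-likelihood of the observed LoS under the
#' (hierarchical) truncated-normal regression at a given parameter point:
#' the product over levels and records of
#' `Normal(y_i; beta0[l] + x_i' beta[l, ], sigma)` restricted to the
#' nonnegative half-line.
#'
#' @param model A [los_model()].
#' @param beta0 Numeric vector of per-level intercepts.
#' @param beta Levels x features coefficient matrix.
#' @param sigma Noise scale (`> 0`).
#' @return The scalar log-likelihood.
#' @export
los_loglik <- function(model, beta0, beta, sigma) {
  stopifnot(inherits(model, "los_model"))
  beta <- matrix(beta, model$n_levels, ncol(model$X))
  mu <- beta0[model$level + 1L] +
    rowSums(model$X * beta[model$level + 1L, , drop = FALSE])
  sum(dnorm(model$y, mu, sigma, log = TRUE) -
        pnorm(mu / sigma, log.p = TRUE))
}

#' Per-level coefficient summary tables
#'
#' Posterior mean and standard deviation of every coefficient, one table per
#' level, rows ordered by decreasing absolute mean, with a formatted
#' `mean +/- sd` label (3 decimals).
#'
#' @param samples A `los_posterior`.
#' @return A tibble with `level`, `parameter`, `estimate`, `std.error`,
#'   `label`.
#' @export
summarize_coefficients <- function(samples) {
  stopifnot(inherits(samples, "los_posterior"))
  model <- samples$model
  m <- as_draws_matrix(samples)
  purrr::map_dfr(seq_len(model$n_levels) - 1L, function(l) {
    cols <- sprintf("beta[%d,%s]", l, model$features)
    est <- colMeans(m[, cols, drop = FALSE])
    se <- apply(m[, cols, drop = FALSE], 2, sd)
    tibble::tibble(
      level = l, parameter = model$features,
      estimate = unname(est), std.error = unname(se),
      label = sprintf("%.3f ± %.3f", est, se)
    ) |>
      dplyr::arrange(dplyr::desc(abs(.data$estimate)))
  })
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy posterior summaries
#'
#' @param x A `los_posterior`.
#' @param conf_level Central credible mass.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`, `rhat`.
#' @export
tidy.los_posterior <- function(x, conf_level = 0.9, ...) {
  m <- as_draws_matrix(x)
  a <- (1 - conf_level) / 2
  qs <- apply(m, 2, quantile, probs = c(a, 1 - a), names = FALSE)
  tibble::tibble(
    term = colnames(m),
    estimate = unname(colMeans(m)),
    std.error = unname(apply(m, 2, sd)),
    conf.low = qs[1, ],
    conf.high = qs[2, ],
    rhat = rhat(x)$rhat
  )
}

#' One-row posterior fit summary
#'
#' @param x A `los_posterior`.
#' @param ... Unused.
#' @export
glance.los_posterior <- function(x, ...) {
  r <- rhat(x)
  tibble::tibble(
    kind = x$model$kind,
    chains = x$chains, draws = x$n_draws, tune = x$tune,
    divergences = x$divergence_count,
    max_rhat = max(r$rhat),
    sigma = mean(as_draws_matrix(x)[, "sigma"])
  )
}

#' Trace plot of posterior draws
#'
#' @param object A `los_posterior`.
#' @param parameters Parameter names to display (default: intercepts and
#'   noise scale).
#' @param ... Unused.
#' @export
autoplot.los_posterior <- function(object, parameters = NULL, ...) {
  parameters <- parameters %||%
    c(sprintf("beta0[%d]", seq_len(object$model$n_levels) - 1L), "sigma")
  df <- purrr::imap_dfr(object$draws, function(m, k) {
    tibble::as_tibble(m[, parameters, drop = FALSE]) |>
      dplyr::mutate(.chain = factor(k), .iteration = dplyr::row_number()) |>
      tidyr::pivot_longer(dplyr::all_of(parameters),
                          names_to = "parameter", values_to = "value")
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$.iteration, .data$value,
                                   colour = .data$.chain)) +
    ggplot2::geom_line(alpha = 0.7, linewidth = 0.3) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "Iteration", y = NULL, colour = "Chain") +
    ggplot2::theme_minimal()
}

#' Serialize posterior draws
#'
#' `write_posterior()` stores the draws as a flat CSV in chain/draw long
#' layout together with a JSON summary (sampler configuration, per-parameter
#' posterior mean, sd and split-chain diagnostic); `read_posterior_draws()`
#' restores the draws as a list of per-chain matrices.
#'
#' @param samples A `los_posterior`.
#' @param dir Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_posterior <- function(samples, dir) {
  stopifnot(inherits(samples, "los_posterior"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  long <- purrr::imap_dfr(samples$draws, function(m, k) {
    dplyr::bind_cols(
      tibble::tibble(chain = k, draw = seq_len(nrow(m))),
      tibble::as_tibble(m)
    )
  })
  utils::write.csv(long, file.path(dir, "draws.csv"), row.names = FALSE)
  td <- tidy(samples)
  jsonlite::write_json(
    list(
      kind = samples$model$kind,
      chains = samples$chains, draws = samples$n_draws, tune = samples$tune,
      divergence_count = samples$divergence_count, seed = samples$seed,
      parameters = td
    ),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname write_posterior
#' @export
read_posterior_draws <- function(dir) {
  long <- utils::read.csv(file.path(dir, "draws.csv"), check.names = FALSE)
  purrr::map(sort(unique(long$chain)), function(k) {
    m <- as.matrix(long[long$chain == k, setdiff(names(long), c("chain", "draw"))])
    rownames(m) <- NULL
    m
  })
}
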