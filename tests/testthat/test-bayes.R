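test_that("level assignment uses half-open bins on the standard edges", {
  expect_equal(assign_level(5), 0L)
  expect_equal(assign_level(10), 1L)
  expect_equal(assign_level(30), 3L)
  expect_equal(assign_level(c(0, 9.99, 19.99, 29.99, 65)), c(0L, 0L, 1L, 2L, 3L))
  expect_error(assign_level(-1), "nonnegative")
})

test_that("model construction instantiates the documented parameter counts", {
  feats <- los_selected_features()
  X <- matrix(runif(50 * 44), 50, 44, dimnames = list(NULL, feats))
  y <- runif(50, 1, 40)
  hbm <- los_model(X, y, kind = "hbm")
  expect_equal(n_parameters(hbm),
               list(intercepts = 4L, coefficients = 176L, noise = 1L))
  sbm <- los_model(X, y, kind = "sbm")
  expect_equal(n_parameters(sbm),
               list(intercepts = 1L, coefficients = 44L, noise = 1L))
  expect_error(los_model(X, y, kind = "hbm", level = rep(7L, 50)), "0..3")
  X[1, 1] <- NA
  expect_error(los_model(X, y), "non-finite")
})

test_that("the hierarchical log-likelihood matches an independent evaluator", {
  set.seed(31)
  n <- 60; p <- 3
  X <- matrix(runif(n * p), n, p)
  y <- runif(n, 0.5, 35)
  model <- los_model(X, y, kind = "hbm")

  # independent evaluator: per-level loop over scalar densities written
  # directly from the truncated-normal form
  ref_loglik <- function(beta0, beta, sigma) {
    total <- 0
    for (l in 0:3) {
      for (i in which(model$level == l)) {
        mu <- beta0[l + 1] + sum(X[i, ] * beta[l + 1, ])
        total <- total - 0.5 * ((y[i] - mu) / sigma)^2 -
          log(sigma) - 0.5 * log(2 * pi) - log(stats::pnorm(mu / sigma))
      }
    }
    total
  }
  for (k in 1:50) {
    beta0 <- runif(4, 2, 30)
    beta <- matrix(rnorm(12), 4, 3)
    sigma <- runif(1, 0.5, 4)
    expect_equal(los_loglik(model, beta0, beta, sigma),
                 ref_loglik(beta0, beta, sigma), tolerance = 1e-10)
  }

  # single-level reduction: HBM with all records in one level equals the SBM
  # log-density at identical parameter values
  m1 <- los_model(X, y, kind = "hbm", level = rep(0L, n))
  ms <- los_model(X, y, kind = "sbm")
  b <- rnorm(p)
  expect_equal(
    los_loglik(m1, c(8, 0, 0, 0), rbind(b, 0, 0, 0), 2),
    los_loglik(ms, 8, matrix(b, 1), 2),
    tolerance = 1e-12
  )
})

test_that("degenerate data pins the posterior at zero under tight priors", {
  X <- matrix(runif(200 * 2), 200, 2)
  m <- los_model(X, rep(0, 200), kind = "sbm",
                 priors = prior_spec(fixed_mu = 0, fixed_sigma = 0.01,
                                     fixed_noise = 1))
  post <- sample_posterior(m, chains = 2, draws = 400, tune = 200, seed = 1)
  td <- tidy(post)
  coefs <- td[grepl("^beta", td$term), ]
  expect_true(all(abs(coefs$estimate) < 0.02))
})

test_that("posterior sampling is reproducible and records its configuration", {
  coh <- generate_cohort(model_faithful_spec(150, n_features = 2, seed = 3))
  m <- los_model(as.matrix(coh$table[, c("x1", "x2")]), coh$table$LOS,
                 kind = "hbm", level = coh$table$level)
  a <- sample_posterior(m, chains = 2, draws = 80, tune = 60, seed = 12)
  b <- sample_posterior(m, chains = 2, draws = 80, tune = 60, seed = 12)
  expect_identical(a$draws, b$draws)
  expect_false(identical(
    a$draws, sample_posterior(m, chains = 2, draws = 80, tune = 60, seed = 13)$draws
  ))
  expect_equal(a$divergence_count, 0L)
  expect_equal(dim(a$draws[[1]]), c(80L, 4L + 8L + 5L))
  expect_error(sample_posterior(m, chains = 1), "2 chains")
})

test_that("split-chain diagnostic behaves on constant, iid and shifted chains", {
  const <- replicate(3, matrix(2.5, 100, 1, dimnames = list(NULL, "p")),
                     simplify = FALSE)
  expect_equal(rhat(const)$rhat, 1)

  set.seed(5)
  iid <- replicate(4, matrix(rnorm(3000), ncol = 1, dimnames = list(NULL, "p")),
                   simplify = FALSE)
  expect_lt(abs(rhat(iid)$rhat - 1), 0.01)

  shifted <- list(
    matrix(rnorm(1000, 0), ncol = 1, dimnames = list(NULL, "p")),
    matrix(rnorm(1000, 5), ncol = 1, dimnames = list(NULL, "p"))
  )
  expect_gt(rhat(shifted)$rhat, 1.1)
  expect_error(rhat(shifted[1]), "2 chains")
})

test_that("untruncated-limit posterior matches the conjugate closed form", {
  set.seed(3)
  n <- 400; p <- 3; tau <- 10; sigma <- 1
  X <- matrix(runif(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  y <- drop(50 + X %*% c(2, -1.5, 1) + rnorm(n, 0, sigma))  # far from zero
  m <- los_model(X, y, kind = "sbm",
                 priors = prior_spec(fixed_mu = 0, fixed_sigma = tau,
                                     fixed_noise = sigma))
  post <- sample_posterior(m, chains = 4, draws = 1500, tune = 500, seed = 5)
  td <- tidy(post)
  terms <- c("beta0[0]", paste0("beta[0,x", 1:p, "]"))
  est <- td$estimate[match(terms, td$term)]
  # independent conjugate oracle: (Z'Z/s^2 + I/tau^2)^{-1} Z'y/s^2
  Z <- cbind(1, X)
  closed <- drop(solve(t(Z) %*% Z / sigma^2 + diag(p + 1) / tau^2,
                       t(Z) %*% y / sigma^2))
  mcse <- td$std.error[match(terms, td$term)] / sqrt(post$chains * post$n_draws)
  expect_true(all(abs(est - closed) < 3 * mcse * sqrt(20)))  # conservative ESS
  expect_true(all(abs(est - closed) < 0.02))
})

test_that("the sampler agrees with brute-force grid integration", {
  set.seed(14)
  n <- 100
  X <- matrix(runif(n), n, 1, dimnames = list(NULL, "x"))
  y <- numeric(n)
  mu_true <- 1.2 + 1.5 * X[, 1]
  for (i in seq_len(n)) {
    repeat { d <- rnorm(1, mu_true[i], 1.2); if (d > 0) { y[i] <- d; break } }
  }
  m <- los_model(X, y, kind = "sbm",
                 priors = prior_spec(fixed_mu = 0, fixed_sigma = 5))
  post <- sample_posterior(m, chains = 4, draws = 3000, tune = 1000, seed = 6)
  td <- tidy(post)
  ours <- td$estimate[match(c("beta0[0]", "beta[0,x]", "sigma"), td$term)]

  grid <- expand.grid(
    b0 = seq(-1, 3.5, length.out = 50),
    b1 = seq(-1.5, 4.5, length.out = 50),
    s = seq(0.6, 2.4, length.out = 40)
  )
  lp <- mapply(function(b0, b1, s) {
    mu <- b0 + b1 * X[, 1]
    sum(dnorm(y, mu, s, log = TRUE) - pnorm(mu / s, log.p = TRUE)) +
      dnorm(b0, 0, 5, log = TRUE) + dnorm(b1, 0, 5, log = TRUE) -
      s^2 / (2 * 25)
  }, grid$b0, grid$b1, grid$s)
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  oracle <- c(sum(w * grid$b0), sum(w * grid$b1), sum(w * grid$s))
  expect_equal(unname(ours), oracle, tolerance = 0.05)
})

test_that("the sampler agrees with an external MCMC oracle when truncation bites", {
  set.seed(9)
  n <- 300
  X <- matrix(runif(n), n, 1, dimnames = list(NULL, "x"))
  y <- numeric(n)
  mu_true <- 1 + 2 * X[, 1]
  for (i in seq_len(n)) {
    repeat { d <- rnorm(1, mu_true[i], 1.5); if (d > 0) { y[i] <- d; break } }
  }
  m <- los_model(X, y, kind = "sbm",
                 priors = prior_spec(fixed_mu = 0, fixed_sigma = 5))
  post <- sample_posterior(m, chains = 4, draws = 3000, tune = 1000, seed = 2)
  td <- tidy(post)
  ours <- td$estimate[match(c("beta0[0]", "beta[0,x]", "sigma"), td$term)]

  requireNamespace("rjags", quietly = TRUE)
  mc <- "model { for (i in 1:n) { y[i] ~ dnorm(b0 + b1 * x[i], tau) T(0,) }
    b0 ~ dnorm(0, 0.04); b1 ~ dnorm(0, 0.04)
    sigma ~ dnorm(0, 0.04) T(0,); tau <- 1 / (sigma * sigma) }"
  jm <- rjags::jags.model(
    textConnection(mc), data = list(y = y, x = X[, 1], n = n),
    n.chains = 2, quiet = TRUE,
    inits = list(list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 1),
                 list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 2))
  )
  update(jm, 2000, progress.bar = "none")
  s <- rjags::coda.samples(jm, c("b0", "b1", "sigma"), 8000,
                           progress.bar = "none")
  theirs <- colMeans(as.matrix(s))[c("b0", "b1", "sigma")]
  expect_equal(unname(ours), unname(theirs), tolerance = 0.05)
})

test_that("predictions respect truncation, modes and the noiseless limit", {
  truth <- ground_truth(beta0 = c(5, 15, 25, 34),
                        beta = matrix(rep(c(2, -1), each = 4), 4, 2),
                        sigma = 1)
  coh <- generate_cohort(model_faithful_spec(
    600, n_features = 2, seed = 21, truth = truth
  ))
  X <- as.matrix(coh$table[, c("x1", "x2")])
  m <- los_model(X, coh$table$LOS, kind = "hbm", level = coh$table$level)
  post <- sample_posterior(m, chains = 2, draws = 300, tune = 300, seed = 4)
  pr <- predict(post, X, level_mode = "oracle", y_test = coh$table$LOS)
  expect_true(all(pr$.pred >= 0))
  expect_true(all(pr$.lower <= pr$.pred + 1e-9))
  expect_true(all(pr$.pred <= pr$.upper + 1e-9))
  expect_error(predict(post, X, level_mode = "oracle"), "y_test")

  marg <- predict(post, X, level_mode = "marginal")
  expect_true(all(marg$.pred >= 0))
  # oracle predictions track the level structure, marginal ones cannot
  expect_gt(sd(pr$.pred), sd(marg$.pred))

  # single-level model: oracle and marginal predictions coincide
  ms <- los_model(X, coh$table$LOS, kind = "sbm")
  ps <- sample_posterior(ms, chains = 2, draws = 200, tune = 200, seed = 4)
  po <- predict(ps, X, level_mode = "oracle", y_test = coh$table$LOS)
  pm <- predict(ps, X, level_mode = "marginal")
  expect_equal(po$.pred, pm$.pred, tolerance = 1e-12)

  # noiseless limit: with parameters pinned at truth and sigma tiny, the
  # posterior predictive mean equals the linear predictor
  m0 <- los_model(X, coh$table$LOS, kind = "hbm", level = coh$table$level,
                  priors = prior_spec(fixed_noise = 1e-6))
  # inject a synthetic posterior holding the true parameters in every draw
  post0 <- sample_posterior(m0, chains = 2, draws = 2, tune = 2, seed = 1)
  for (k in seq_along(post0$draws)) {
    d <- post0$draws[[k]]
    d[, sprintf("beta0[%d]", 0:3)] <- rep(truth$beta0, each = nrow(d))
    for (l in 0:3) {
      d[, sprintf("beta[%d,x%d]", l, 1:2)] <-
        rep(truth$beta[l + 1, ], each = nrow(d))
    }
    d[, "sigma"] <- 1e-6
    post0$draws[[k]] <- d
  }
  pr0 <- predict(post0, X, level_mode = "oracle", y_test = coh$table$LOS)
  lin <- truth$beta0[coh$table$level + 1] +
    rowSums(X * truth$beta[coh$table$level + 1, ])
  expect_equal(pr0$.pred, lin, tolerance = 1e-6)
})

test_that("coefficient summaries order by magnitude and use sample sd", {
  coh <- generate_cohort(model_faithful_spec(120, n_features = 3, seed = 6))
  m <- los_model(as.matrix(coh$table[, paste0("x", 1:3)]), coh$table$LOS,
                 kind = "hbm", level = coh$table$level)
  post <- sample_posterior(m, chains = 2, draws = 50, tune = 50, seed = 2)
  # constant injected draws give an exact mean +/- 0
  for (k in seq_along(post$draws)) {
    post$draws[[k]][, grepl("^beta\\[", colnames(post$draws[[k]]))] <- 0.5
  }
  tab <- summarize_coefficients(post)
  expect_equal(nrow(tab), 4 * 3)
  expect_true(all(tab$estimate == 0.5))
  expect_true(all(tab$std.error == 0))
  expect_equal(tab$label[1], "0.500 ± 0.000")

  # two-point draws give the sample-sd convention
  m2 <- post
  half <- matrix(rep(c(0, 1), length.out = 100), 50, 2)
  for (k in 1:2) m2$draws[[k]][, "beta[0,x1]"] <- half[, k]
  tab2 <- summarize_coefficients(m2)
  row <- tab2[tab2$level == 0 & tab2$parameter == "x1", ]
  expect_equal(row$estimate, 0.5)
  expect_equal(row$std.error, sd(rep(c(0, 1), 50)), tolerance = 1e-12)
})

test_that("tidy and glance expose the broom-style surfaces", {
  coh <- generate_cohort(model_faithful_spec(150, n_features = 2, seed = 5))
  m <- los_model(as.matrix(coh$table[, c("x1", "x2")]), coh$table$LOS,
                 kind = "hbm", level = coh$table$level)
  post <- sample_posterior(m, chains = 2, draws = 100, tune = 100, seed = 9)
  td <- tidy(post)
  expect_named(td, c("term", "estimate", "std.error", "conf.low",
                     "conf.high", "rhat"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  g <- glance(post)
  expect_equal(g$chains, 2L)
  expect_equal(g$divergences, 0L)
  p <- ggplot2::ggplot_build(autoplot(post))
  expect_s3_class(p$plot, "ggplot")

  dir <- withr::local_tempdir()
  write_posterior(post, dir)
  back <- read_posterior_draws(dir)
  expect_equal(back[[1]], unname(post$draws[[1]]), ignore_attr = TRUE,
               tolerance = 1e-12)
})
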