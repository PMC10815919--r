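test_that("inner split partitions the training indices at the same ratio", {
  train <- sort(sample(1:6000, 4290))
  s <- inner_split(train, seed = 3)
  expect_length(s$fit, 3432L)
  expect_length(s$validate, 858L)
  expect_length(intersect(s$fit, s$validate), 0L)
  expect_setequal(c(s$fit, s$validate), train)
  expect_identical(inner_split(train, seed = 3), s)
  expect_error(inner_split(1:5), "at least 10")
})

test_that("the base model memorizes exact structure and is seeded", {
  fx <- signal_fixture(n = 200, sd = 0)  # y = 2 * x1 exactly
  deep <- list(min.node.size = 1, mtry = 6, replace = FALSE,
               sample.fraction = 1)
  fit <- do.call(fit_base_model,
                 c(list(fx$X, fx$y, seed = 5, num_trees = 300), deep))
  expect_lt(rmse(fx$y, predict(fit, fx$X)), 0.05 * sd(fx$y))
  fit2 <- do.call(fit_base_model,
                  c(list(fx$X, fx$y, seed = 5, num_trees = 300), deep))
  expect_identical(predict(fit, fx$X), predict(fit2, fx$X))

  const <- fit_base_model(fx$X, rep(4, 200), seed = 1)
  expect_equal(unique(predict(const, fx$X)), 4)
  expect_error(fit_base_model(fx$X[1, , drop = FALSE], 1), "2 rows")
})

test_that("permutation importance scores signal positive and constants exactly zero", {
  fx <- signal_fixture(n = 300, sd = 0.3, seed = 2)
  X <- fx$X
  X$const <- 1
  fit <- fit_base_model(X[1:240, ], fx$y[1:240], seed = 7)
  rep <- permutation_importance(fit, X[241:300, ], fx$y[241:300], K = 20, seed = 7)
  expect_identical(rep$importance[rep$feature == "const"], 0)
  expect_gt(rep$importance[rep$feature == "x1"], 0)
  expect_equal(unique(rep$baseline_score), rep$baseline_score[1])
  expect_equal(rep$importance, rep$mean_augmented_score - rep$baseline_score)
  expect_identical(rep$selected, rep$importance > 0)
  # single-feature entry point agrees with the report
  expect_equal(pfi_score(fit, X[241:300, ], fx$y[241:300], "x1", K = 20, seed = 7),
               rep$importance[rep$feature == "x1"])
  expect_error(pfi_score(fit, X[241:300, ], fx$y[241:300], "nope"), "nope")
})

test_that("noise features are never systematically selected over replicates", {
  # A permuted truly-null feature has importance with sign probability ~1/2
  # (the permutation preserves its marginal exactly), so per-replicate
  # selection of a noise feature is a fair coin; the stable property is the
  # absence of any systematic preference: noise importances centred on zero,
  # far below the signal feature, with no noise feature selected in more
  # than half the replicates.
  rates <- matrix(FALSE, 20, 5)
  gaps <- numeric(20)
  imps <- matrix(0, 20, 5)
  for (s in 1:20) {
    set.seed(s)
    X <- as.data.frame(matrix(runif(500 * 6), 500))
    names(X) <- c("x1", paste0("noise", 1:5))
    y <- 2 * X$x1 + rnorm(500, 0, 0.5)
    split <- split_matrix(500, seed = s)
    fit <- fit_base_model(X[split$train, ], y[split$train], seed = s)
    rep <- permutation_importance(fit, X[split$test, ], y[split$test],
                                  K = 20, seed = s)
    sel <- select_features(rep)
    rates[s, ] <- paste0("noise", 1:5) %in% sel
    imps[s, ] <- rep$importance[match(paste0("noise", 1:5), rep$feature)]
    gaps[s] <- rep$importance[rep$feature == "x1"] - max(imps[s, ])
  }
  expect_true(all(colMeans(rates) <= 0.5))
  expect_true(all(gaps > 0))                       # signal dominates everywhere
  expect_lt(abs(mean(imps)), 3 * sd(imps) / sqrt(length(imps)) + 1e-3)
})

test_that("null features average toward zero as K grows", {
  fx <- signal_fixture(n = 300, sd = 0.3, seed = 4)
  fit <- fit_base_model(fx$X[1:240, ], fx$y[1:240], seed = 1)
  s_small <- vapply(1:6, function(s) {
    pfi_score(fit, fx$X[241:300, ], fx$y[241:300], "noise1", K = 2, seed = s)
  }, numeric(1))
  s_large <- vapply(1:6, function(s) {
    pfi_score(fit, fx$X[241:300, ], fx$y[241:300], "noise1", K = 40, seed = s)
  }, numeric(1))
  expect_lt(sd(s_large), sd(s_small))
  expect_lt(abs(mean(s_large)), 0.2)
})

test_that("selection keeps positive scores ordered with alphabetical ties", {
  rep <- tibble::tibble(
    feature = c("a", "b", "c", "d", "e"),
    K = 10L, baseline_score = 1,
    mean_augmented_score = 1 + c(0.3, 0.1, -0.2, 0.1, 0),
    importance = c(0.3, 0.1, -0.2, 0.1, 0),
    selected = c(TRUE, TRUE, FALSE, TRUE, FALSE)
  )
  expect_equal(select_features(rep), c("a", "b", "d"))
  rep$importance <- c(-1, -0.5, -0.2, 0, 0)
  expect_length(select_features(rep), 0L)
  expect_error(select_features(rep[0, ]), "Empty")
})

test_that("the packaged reference list has 44 features present in the cohort", {
  feats <- los_selected_features()
  expect_length(feats, 44L)
  expect_false(any(duplicated(feats)))
  tab <- tiny_clinical_table(n = 20, seed = 1)
  staged <- build_target(impute_bp(impute_bmi(tab)))
  expect_true(all(feats %in% names(staged)))
})
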