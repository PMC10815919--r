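test_that("BMI imputation uses the weight/height formula and never edits present values", {
  tb <- tibble::tibble(
    BMI = c(NA, 30, NA, NA),
    weight = c(71.87, 100, 36, NA),
    height = c(163.6, 180, 123, 170)
  )
  out <- impute_bmi(tb)
  expect_equal(out$BMI[1], 26.85, tolerance = 0.0002)
  expect_equal(out$BMI[2], 30)
  expect_equal(out$BMI[3], 23.80, tolerance = 0.0002)
  expect_true(is.na(out$BMI[4]))           # no references: left for row drop
  expect_identical(impute_bmi(out), out)   # idempotent
})

test_that("blood-pressure imputation is conditional on hypertension", {
  tb <- tibble::tibble(
    hypertension = c("Yes", "No", "Yes", NA),
    BPsystolic = c(NA, NA, 130, NA),
    diastolic = c(72, 68, NA, 70)
  )
  out <- impute_bp(tb)
  expect_equal(out$BPsystolic[1], 124)
  expect_equal(out$BPsystolic[2], 117)
  expect_equal(out$BPsystolic[3], 130)     # present value untouched
  expect_true(is.na(out$BPsystolic[4]))    # reference missing: left for drop
  expect_equal(out$diastolic[3], 72)       # only hypertensive donor present

  # means estimated from designated training rows only
  tb2 <- tibble::tibble(
    hypertension = rep(c("Yes", "No"), each = 4),
    BPsystolic = c(120, 130, NA, 140, 100, 110, NA, 150),
    diastolic = rep(70, 8)
  )
  out2 <- impute_bp(tb2, hyper_mean = NULL, normo_mean = NULL, train = c(1, 2, 5, 6))
  expect_equal(out2$BPsystolic[3], 125)    # mean(120, 130)
  expect_equal(out2$BPsystolic[7], 105)    # mean(100, 110)
})

test_that("sparse-row removal enforces the 5% benchmark", {
  tb <- tibble::tibble(a = rnorm(100), b = rnorm(100))
  expect_identical(drop_sparse_rows(tb), tb)
  tb$b[1:3] <- NA
  expect_equal(nrow(drop_sparse_rows(tb)), 97L)
  tb$b[4:6] <- NA
  expect_error(drop_sparse_rows(tb), "6.0%")
})

test_that("target construction adds the components and prunes bookkeeping columns", {
  tb <- tibble::tibble(
    TempSNO = 1:3,
    date_of_admission = as.Date("2018-01-01") + 0:2,
    date_of_surgery = as.Date("2018-01-03") + 0:2,
    date_of_discharge = as.Date("2018-01-09") + 0:2,
    admission_to_surgery = c(2L, 3L, 1L),
    LOS_Surgery_to_discharge = c(6L, 4L, 9L),
    weight = 70, height = 170, BMI = 24.2, patient_age = 60
  )
  out <- build_target(tb)
  expect_equal(out$LOS, c(8, 7, 10))
  expect_named(out, c("BMI", "patient_age", "LOS"))
  tb$admission_to_surgery[1] <- -1L
  expect_error(build_target(tb), "nonnegative")
})

test_that("the packaged cohort prepares to the documented shape", {
  tab <- tiny_clinical_table(n = 500, seed = 13)
  staged <- build_target(drop_sparse_rows(impute_bp(impute_bmi(tab))))
  expect_equal(ncol(staged), 61L)  # 60 features + target
})

test_that("label encoding is alphabetical from zero and round-trips", {
  tb <- tibble::tibble(
    flag = c("Yes", "No", "Yes"),
    nyha = c("NYHA I", "Not applicable", "NYHA IV"),
    x = c(1.5, 2.5, 3.5),
    LOS = c(5, 8, 12)
  )
  mat <- encode(tb)
  expect_equal(mat$values$flag, c(1, 0, 1))  # {No: 0, Yes: 1}
  nyha_map <- mat$columns$encoding[[which(mat$columns$name == "nyha")]]
  expect_equal(sort(unname(nyha_map)), seq_along(nyha_map) - 1L)
  expect_equal(mat$values$x, tb$x)
  expect_equal(mat$target, tb$LOS)
  expect_equal(as.data.frame(decode(mat)),
               as.data.frame(tb[, c("flag", "nyha", "x")]))

  full_nyha <- c("Not applicable", paste("NYHA", c("I", "II", "III", "IV")))
  tb2 <- tibble::tibble(nyha = full_nyha, LOS = 1:5)
  m2 <- encode(tb2)
  expect_equal(sort(m2$values$nyha), 0:4)

  newdata <- tibble::tibble(flag = "Maybe", nyha = "NYHA I", x = 1, LOS = 2)
  enc <- setNames(mat$columns$encoding, mat$columns$name)
  expect_error(encode(newdata, encoders = enc), "Maybe")
  expect_error(encode(tibble::tibble(a = c("x", NA), LOS = 1:2)), "missing")
})

test_that("the split is a seeded disjoint 80/20 partition", {
  s <- split_matrix(100, seed = 7)
  expect_length(s$train, 80L)
  expect_length(s$test, 20L)
  expect_length(intersect(s$train, s$test), 0L)
  expect_setequal(c(s$train, s$test), 1:100)
  expect_identical(split_matrix(100, seed = 7), s)
  expect_false(identical(split_matrix(100, seed = 8)$train, s$train))
  big <- split_matrix(5363, seed = 1)
  expect_length(big$train, 4290L)
  expect_length(big$test, 1073L)
})

test_that("min-max scaling is fitted on training rows without clipping", {
  mat <- encode(tibble::tibble(a = c(2, 4, 6, 8), b = c(5, 5, 5, 9), LOS = 1:4))
  sc <- scale_fit(mat, train = 1:3)
  out <- scale_apply(mat, sc)
  expect_equal(out$values$a, c(0, 0.5, 1, 1.5))  # test value beyond [0, 1]
  expect_equal(out$values$b[1:3], c(0, 0, 0))    # constant training column
})

test_that("no test-row statistic leaks into fitted preprocessing parameters", {
  tab <- tiny_clinical_table(n = 400, seed = 17)
  prep <- preprocess_cohort(tab, seed = 9)
  te <- prep$split$test

  # rebuild the raw staged table the pipeline saw, perturb only test rows
  tab2 <- tab
  cont <- c("patient_age", "last_wbc_count", "BPsystolic", "diastolic")
  staged <- impute_bmi(tab)
  probe <- impute_bp(staged, hyper_mean = 0, normo_mean = 0)
  keep <- which(stats::complete.cases(probe))
  rows_te <- keep[te]
  for (nm in cont) tab2[[nm]][rows_te] <- tab2[[nm]][rows_te] + 40
  prep2 <- preprocess_cohort(tab2, seed = 9)

  expect_identical(prep2$split, prep$split)
  expect_equal(as.data.frame(prep2$scaler), as.data.frame(prep$scaler))
  expect_identical(prep2$matrix$columns$encoding, prep$matrix$columns$encoding)
  # training rows themselves are untouched by the perturbation
  expect_equal(prep2$matrix$values[prep$split$train, ],
               prep$matrix$values[prep$split$train, ])
})
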