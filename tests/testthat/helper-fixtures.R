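# Small in-code fixtures shared across test files.

tiny_clinical_table <- function(n = 40, seed = 1) {
  spec <- default_cohort_spec(seed)
  spec$n_patients <- as.integer(n)
  generate_cohort(spec)$table
}

# A linear-signal regression fixture: y = 2 * x1 + noise, plus pure-noise
# features, for the permutation-importance properties.
signal_fixture <- function(n = 200, noise_features = 5, sd = 0.5, seed = 1) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    X <- as.data.frame(matrix(runif(n * (noise_features + 1)), n))
    names(X) <- c("x1", paste0("noise", seq_len(noise_features)))
    list(X = X, y = 2 * X$x1 + rnorm(n, 0, sd))
  })
}
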