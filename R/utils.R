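#' @importFrom rlang abort warn .data
#' @importFrom stats predict coef lm median pnorm qnorm quantile rnorm runif
#'   sd var rbinom rnbinom setNames complete.cases dnorm
#' @importFrom utils head modifyList
#' @import Rcpp
#' @useDynLib bayeslos, .registration = TRUE
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards so library calls stay side-effect free.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Deterministic per-stage seed derivation from a master seed; stays < 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1013L * as.integer(offset)) %% 2147483647L
}

# Inverse-CDF draw from Normal(mean, sd) truncated to [lower, upper].
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (any(sd < 0)) abort("`sd` must be nonnegative.")
  if (all(sd == 0)) return(pmin(pmax(rep_len(mean, n), lower), upper))
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

rmse <- function(actual, predicted) sqrt(mean((actual - predicted)^2))

`%||%` <- function(x, y) if (is.null(x)) y else x
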