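# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# stream. All exported stochastic operations funnel their seed through this.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic per-subject seed streams derived from one root seed.
# Kept well below 2^31.
derive_seed <- function(root, i, j = 0L) {
  (as.integer(root) + 7919L * as.integer(i) + 104729L * as.integer(j)) %% 2000000011L
}

# Round-half-up to integer (unlike round()'s banker's rounding).
round_half_up <- function(x) floor(x + 0.5)

# Trapezoidal integral of y over x (x strictly increasing).
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

sample_skewness <- function(x) {
  x <- x - mean(x)
  s <- sqrt(mean(x^2))
  if (s == 0) return(0)
  mean(x^3) / s^3
}

# Standardize columns to mean 0, sd 1 (population sd); errors on zero variance.
zscore_cols <- function(m, what = "map") {
  m <- sweep(m, 2, colMeans(m))
  s <- sqrt(colMeans(m^2))
  if (any(s == 0)) stop("zero-variance ", what, " cannot be z-scored")
  sweep(m, 2, s, "/")
}

# Pearson correlation between columns of a and columns of b (population
# normalization; exact for correlation since it cancels).
cross_cor <- function(a, b) {
  a <- zscore_cols(as.matrix(a))
  b <- zscore_cols(as.matrix(b))
  crossprod(a, b) / nrow(a)
}
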