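# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Pairwise squared Euclidean distances between rows of a and rows of b.
# Cross products are clamped at zero to absorb rounding.
sq_dist <- function(a, b) {
  an <- rowSums(a * a)
  bn <- rowSums(b * b)
  d <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d[d < 0] <- 0
  d
}

# Column variances without apply() overhead.
col_vars <- function(x) {
  n <- nrow(x)
  if (n < 2) return(rep(0, ncol(x)))
  cm <- colMeans(x)
  (colSums(x * x) - n * cm * cm) / (n - 1)
}

stopifnot_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) stop(what, " contains non-finite values")
}
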