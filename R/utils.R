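#' @importFrom rlang abort warn %||%
#' @importFrom stats prcomp predict rbinom rnorm runif sd var setNames quantile
#' @importFrom utils head write.csv read.csv
NULL

# Derive a reproducible child seed from a parent seed and an index.
# Kept strictly below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483647)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be positive.", name))
  invisible(x)
}

# Axis order is (x, y, z) with 0-based voxel indices and half-open
# intervals [lo, hi) everywhere boxes appear.
assert_triple <- function(x, name, positive = TRUE, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 3L || anyNA(x)) {
    abort(sprintf("`%s` must be a numeric triple.", name))
  }
  if (positive && any(x <= 0)) abort(sprintf("`%s` must be positive.", name))
  if (integer && any(x != round(x))) abort(sprintf("`%s` must be integers.", name))
  invisible(x)
}
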