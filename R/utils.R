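# Small shared helpers.

#' Geometric mean
#'
#' @param x positive numeric vector.
#' @return `exp(mean(log(x)))`.
#' @export
geomean <- function(x) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("geometric mean requires finite, strictly positive values")
  }
  exp(mean(log(x)))
}

#' Geometric standard deviation
#'
#' @param x positive numeric vector.
#' @return `exp(sd(log(x)))`.
#' @export
geosd <- function(x) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("geometric SD requires finite, strictly positive values")
  }
  exp(sd(log(x)))
}

# Natural-space coefficient of variation implied by a log-space SD.
lognormal_cv <- function(sdlog) sqrt(exp(sdlog^2) - 1)

# Deterministic substream seeds below 2^31, derived from a master seed and
# integer indices (trial, arm, ...).  Multiplicative hashing keeps distinct
# index tuples on distinct streams for practical purposes.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  h <- as.double(seed) %% 2147483647
  for (k in idx) {
    h <- (h * 48271 + as.double(k) + 1) %% 2147483647
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a single positive finite number", name))
  }
  invisible(x)
}
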