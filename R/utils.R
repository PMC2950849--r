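# Internal helpers shared across modules.

#' Derive a reproducible child seed from a master seed
#'
#' All randomness in the package flows from one master seed; independent
#' sub-streams (landscape field vs point sampler, per-model fits, per-chain
#' starts) use child seeds derived deterministically from it.
#'
#' @param seed Master seed (integer-like scalar).
#' @param k Stream index (non-negative integer).
#' @return An integer in [0, 2^31 - 2], usable with [set.seed()].
#' @keywords internal
derive_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  # Weyl-style mixing; stays inside 32-bit integer range
  m <- 2147483647
  s <- (abs(seed) %% m)
  for (i in seq_len(2L)) {
    s <- (s * 48271 + 7919 * (k + 1L) + i) %% m
  }
  as.integer(s)
}

#' Numerically stable log(1 + exp(x))
#' @param x Numeric vector.
#' @return log1p(exp(x)) without overflow.
#' @keywords internal
log1pexp <- function(x) {
  out <- numeric(length(x))
  big <- x > 33.3
  mid <- !big & x > -37
  out[big] <- x[big]
  out[mid] <- log1p(exp(x[mid]))
  out[!big & !mid] <- exp(x[!big & !mid])
  out
}

# Clamp probabilities away from 0/1 for chi-square discrepancy terms.
# Clamping events are reported to the caller, never silent.
clamp_prob <- function(p, eps = 1e-12) {
  pmin(pmax(p, eps), 1 - eps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_patchrsf <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "patchrsf_error")))
}
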