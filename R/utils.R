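#' Derive a reproducible child seed from a master seed
#'
#' All stochastic stages of the pipeline draw their own seed from one master
#' seed so that stages can be rerun independently yet deterministically.
#' The derivation is a linear congruential step modulo 2^31 - 1, keeping the
#' result a valid 32-bit integer seed.
#'
#' @param seed master seed (integer-valued scalar, < 2^31).
#' @param stage integer stage index (small non-negative integer).
#' @return an integer seed in \[1, 2^31 - 2\].
#' @export
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(stage), length(stage) == 1L)
  m <- 2147483647
  s <- (abs(as.numeric(seed)) %% m) * 69069 + 1013904223 * (as.numeric(stage) + 1)
  as.integer(s %% (m - 1) + 1)
}

sigmoid <- stats::plogis

#' @importFrom stats qlogis plogis
logit <- stats::qlogis

# strict-inequality quantile bounds with linear interpolation (type 7)
trim_bounds <- function(x, lower_q = 0.01, upper_q = 0.99) {
  x <- x[!is.na(x)]
  stats::quantile(x, probs = c(lower_q, upper_q), names = FALSE, type = 7)
}
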