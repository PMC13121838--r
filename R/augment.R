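## Data-augmentation primitives. The logistic observation noise is
## represented as 2 * psi * N(0, 1) with psi following the
## Kolmogorov-Smirnov law, so that conditional on psi every logistic term
## is Gaussian and the Gibbs blocks stay conjugate.

#' One-sided truncated normal draws
#'
#' Exact draws from `N(mean, sd^2)` truncated to the positive half-line
#' (`positive = TRUE`) or to `(-Inf, 0]`. Uses tail-robust exponential
#' rejection, stable out to `|mean|/sd` of about 30.
#'
#' @param n number of draws.
#' @param mean,sd location and scale (sd > 0).
#' @param positive truncate to (0, Inf) if `TRUE`, else (-Inf, 0].
#' @return Numeric vector of draws.
#' @export
draw_truncated_normal <- function(n, mean = 0, sd = 1, positive = TRUE) {
  if (sd <= 0) stop("sd must be positive")
  cpp_rtnorm(as.integer(n), mean, sd, isTRUE(positive))
}

#' Kolmogorov-Smirnov mixing-scale draws
#'
#' Draws the scale `psi` from its full conditional given the residual
#' `z - eta` of an augmented logistic response, under the K-S prior that
#' makes the normal scale mixture exactly logistic. Rejection sampling
#' with a generalized-inverse-Gaussian proposal and alternating-series
#' squeezing; always terminates.
#'
#' @param residual numeric vector of residuals.
#' @return Numeric vector of positive `psi` draws, with attribute
#'   `accept_rate` (draws per proposal). A warning is emitted if the
#'   acceptance rate drops below 0.3.
#' @export
draw_ks_scale <- function(residual) {
  out <- cpp_ks_scale(as.numeric(residual))
  rate <- length(residual) / out$proposals
  if (length(residual) >= 100 && rate < 0.3)
    warning(sprintf("K-S scale sampler acceptance rate %.2f below 0.3", rate))
  structure(out$psi, accept_rate = rate)
}
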