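## Prior configuration. Objective defaults: flat priors for the person
## mean log-times and the linkage slope; a positivity-truncated,
## essentially flat normal for the growth rates; a log-scale-flat improper
## prior (Gamma(0, 0)) for the time residual precision, whose conditional
## is proper whenever at least one time is observed; and proper diffuse
## Gamma(0.01, 0.01) priors for the hierarchical precisions, where an
## improper 1/lambda prior would risk posterior impropriety.

#' Prior configuration for the DIR-RT sampler
#'
#' Every precision group takes a Gamma(shape `a`, rate `b`) prior with
#' `a = b = 0` meaning the improper p(lambda) proportional to 1/lambda.
#' The growth rate prior is Normal(`beta_mean`, `beta_sd`^2) truncated to
#' nonnegative values. `gamma` and `rho` always take flat priors;
#' `rho_fallback_sd` is the sd of the flagged diffuse draw used if the
#' linkage carries no signal (sum of f^2 numerically zero).
#'
#' @param a_delta,b_delta,a_e,b_e,a_tau,b_tau,a_theta,b_theta,a_eps,b_eps
#'   Gamma hyperparameters per precision group.
#' @param beta_mean,beta_sd truncated-normal hyperparameters for the
#'   growth rates.
#' @param rho_fallback_sd diffuse fallback sd for the slope.
#' @param gamma_mean,gamma_prec,rho_mean,rho_prec optional Gaussian priors
#'   for the person mean log-times and the slope; precision 0 (the
#'   default) keeps the objective flat prior.
#' @return A `dirt_priors` list.
#' @export
dirt_priors <- function(a_delta = 0.01, b_delta = 0.01,
                        a_e = 0.01, b_e = 0.01,
                        a_tau = 0.01, b_tau = 0.01,
                        a_theta = 0.01, b_theta = 0.01,
                        a_eps = 0, b_eps = 0,
                        beta_mean = 0, beta_sd = 100,
                        rho_fallback_sd = 100,
                        gamma_mean = 0, gamma_prec = 0,
                        rho_mean = 0, rho_prec = 0) {
  pr <- list(a_delta = a_delta, b_delta = b_delta, a_e = a_e, b_e = b_e,
             a_tau = a_tau, b_tau = b_tau, a_theta = a_theta,
             b_theta = b_theta, a_eps = a_eps, b_eps = b_eps,
             beta_mean = beta_mean, beta_sd = beta_sd,
             rho_fallback_sd = rho_fallback_sd,
             gamma_mean = gamma_mean, gamma_prec = gamma_prec,
             rho_mean = rho_mean, rho_prec = rho_prec)
  if (any(unlist(pr[1:10]) < 0)) stop("Gamma hyperparameters must be >= 0")
  if (beta_sd <= 0 || rho_fallback_sd <= 0)
    stop("prior scale parameters must be positive")
  structure(pr, class = "dirt_priors")
}

#' Tighter growth-rate prior preset
#'
#' A moderately informative truncated-normal prior for the growth rates,
#' of the kind one switches to when a long chain on simulated data is slow
#' to stabilize; everything else keeps the objective defaults.
#'
#' @param beta_mean,beta_sd truncated-normal hyperparameters.
#' @param ... other overrides passed to [dirt_priors].
#' @return A `dirt_priors` list.
#' @export
dirt_priors_sim <- function(beta_mean = 2, beta_sd = 5, ...) {
  dirt_priors(beta_mean = beta_mean, beta_sd = beta_sd, ...)
}
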