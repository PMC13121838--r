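## Deterministic model functions: observation equations, system equation,
## complete-data log-likelihood and the raw-score ability estimate.

#' Logistic response probability
#'
#' Probability of a correct response under the Rasch-type observation
#' equation with daily and test random effects:
#' \eqn{P(Y = 1) = F(\theta - b + \delta + e)} with \eqn{F} the standard
#' logistic cdf.
#'
#' @param theta ability.
#' @param b item difficulty.
#' @param delta daily random effect (default 0).
#' @param e test random effect (default 0).
#' @return Probability in (0, 1). Inputs recycle as usual.
#' @examples
#' logistic_response_prob(0, 0)            # 0.5
#' logistic_response_prob(1, 0.5)          # plogis(0.5)
#' @export
logistic_response_prob <- function(theta, b, delta = 0, e = 0) {
  eta <- theta - b + delta + e
  if (!all(is.finite(eta))) stop("non-finite input to logistic_response_prob")
  plogis(eta)
}

#' Ability-difficulty linkage function
#'
#' Maps the signed distance between ability and the test's target
#' difficulty into the mean log response time. The monotone linkage is
#' linear, `f(x) = x` (linearity is what keeps the augmented model a
#' dynamic linear model so the ability path can be block-sampled); the
#' inverted-U linkage is quadratic, `f(x) = x^2`, extremal where ability
#' matches difficulty and symmetric about it.
#'
#' @param kind `"monotone"` or `"inverted_u"`.
#' @param theta ability.
#' @param d target (ensemble mean) difficulty of the test.
#' @return `f(theta - d)`.
#' @export
linkage_value <- function(kind, theta, d) {
  kind <- match_linkage(kind)
  x <- theta - d
  if (!all(is.finite(x))) stop("non-finite input to linkage_value")
  if (kind == "monotone") x else x^2
}

match_linkage <- function(kind) {
  if (length(kind) != 1L || !kind %in% c("monotone", "inverted_u"))
    stop("linkage kind must be \"monotone\" or \"inverted_u\"")
  kind
}

linkage_code <- function(kind) if (match_linkage(kind) == "monotone") 0L else 1L

#' Mean log response time
#'
#' The response-time observation equation on the log scale:
#' \eqn{E[\log T] = \gamma - \tau + \rho f(\theta - d)}. The negative sign
#' on the speed deviation encodes that a slower speed means more time.
#'
#' @param gamma person mean log time.
#' @param tau daily speed deviation.
#' @param rho linkage regression slope.
#' @param fval value of the linkage function `f(theta - d)`.
#' @return Mean of the log response time.
#' @export
log_rt_mean <- function(gamma, tau, rho, fval) {
  out <- gamma - tau + rho * fval
  if (!all(is.finite(out))) stop("non-finite input to log_rt_mean")
  out
}

#' Ability transition moments
#'
#' One step of the system equation: ability grows at person rate `beta`
#' scaled by the (capped) time lapse and damped as ability approaches the
#' maturity ceiling `theta_M`; the innovation variance scales with the
#' capped lapse, so a long absence makes the next ability more uncertain.
#'
#' @param theta_prev ability at the previous test date.
#' @param beta average growth rate (>= 0).
#' @param lapse days since the previous test date (> 0).
#' @param cap maximum effective lapse `h_max` (> 0).
#' @param theta_M maturity ceiling (nonzero).
#' @param lambda_theta innovation precision (> 0).
#' @return List with `mean` and `variance` of the next ability. The mean is
#'   linear in `theta_prev` with slope `1 - beta * h / theta_M`.
#' @export
ability_transition <- function(theta_prev, beta, lapse, cap, theta_M,
                               lambda_theta) {
  if (cap <= 0) stop("lapse cap must be positive")
  if (theta_M == 0) stop("theta_M must be nonzero")
  if (any(lapse <= 0)) stop("lapse must be positive")
  if (lambda_theta <= 0) stop("lambda_theta must be positive")
  h <- pmin(lapse, cap)
  list(mean = theta_prev + beta * h * (1 - theta_prev / theta_M),
       variance = h / lambda_theta)
}

#' Complete-data log-likelihood of a DIR-RT state
#'
#' Sums (a) the Bernoulli-logistic log-likelihood of the item responses,
#' (b) the Gaussian log-density of the log response times, and (c) the
#' Gaussian log-densities of the item difficulties around their targets, of
#' the ability transitions, and of the daily, test (sum-to-zero singular
#' normal) and speed random effects.
#'
#' @param dataset a [dirt_data] object.
#' @param state a state list as produced by [init_state] (fields `theta`,
#'   `b`, `delta`, `e`, `tau`, `beta`, `gamma`, `rho`, `lam_delta`,
#'   `lam_e`, `lam_tau`, `lam_theta`, `lam_eps`).
#' @param kind linkage kind (used for the response-time mean).
#' @return A finite scalar log-likelihood.
#' @export
complete_loglik <- function(dataset, state, kind) {
  kind <- match_linkage(kind)
  fl <- flatten_data(dataset)
  s <- state
  stopifnot(length(s$theta) == fl$n_cells, length(s$b) == fl$n_items,
            length(s$delta) == fl$n_cells, length(s$e) == fl$n_tests)
  if (any(c(s$lam_delta, s$lam_e, s$lam_tau, s$lam_theta, s$lam_eps) <= 0))
    stop("precisions must be positive")
  it <- fl$item_test
  ic <- fl$test_cell[it]
  eta <- s$theta[ic] - s$b + s$delta[ic] + s$e[it]
  ll_y <- sum(dbinom(fl$y, 1, plogis(eta), log = TRUE))
  ll_b <- sum(dnorm(s$b, fl$d[it], fl$sigma_b, log = TRUE))

  ll_t <- 0
  if (fl$has_times) {
    tc <- fl$test_cell
    tp <- fl$cell_person[tc]
    f <- linkage_value(kind, s$theta[tc], fl$d)
    mu <- log_rt_mean(s$gamma[tp], s$tau[tc], s$rho, f)
    ll_t <- sum(dnorm(fl$logT, mu, sqrt(1 / s$lam_eps), log = TRUE)) +
      sum(dnorm(s$tau, 0, sqrt(1 / s$lam_tau[fl$cell_person]), log = TRUE))
  }

  ll_tr <- 0
  for (p in seq_len(fl$n_persons)) {
    cells <- which(fl$cell_person == p)
    if (length(cells) < 2) next
    for (j in 2:length(cells)) {
      c1 <- cells[j]
      tr <- ability_transition(s$theta[cells[j - 1]], s$beta[p],
                               fl$cell_lapse[c1], Inf, fl$theta_M,
                               s$lam_theta)
      ll_tr <- ll_tr + dnorm(s$theta[c1], tr$mean, sqrt(tr$variance),
                             log = TRUE)
    }
  }

  ll_delta <- sum(dnorm(s$delta, 0,
                        sqrt(1 / s$lam_delta[fl$cell_person]), log = TRUE))
  # singular sum-to-zero normal for the test effects: on the (S-1)-dim
  # subspace the covariance is (1/lam_e) * identity
  ll_e <- 0
  for (cc in seq_len(fl$n_cells)) {
    es <- s$e[fl$test_cell == cc]
    S <- length(es)
    if (abs(sum(es)) > 1e-8) stop("test effects must sum to zero within a day")
    if (S == 1) next
    lam <- s$lam_e[fl$cell_person[cc]]
    ll_e <- ll_e + 0.5 * (S - 1) * log(lam / (2 * pi)) - 0.5 * lam * sum(es^2)
  }
  ll_y + ll_b + ll_t + ll_tr + ll_delta + ll_e
}

#' Raw-score ability estimate
#'
#' The ability value at which the model-expected test score equals the
#' observed number-correct: solves
#' \eqn{\sum_l F(\hat\theta - b_l) = \sum_l y_l} by bracketed
#' root-finding. Perfect and zero scores have no finite solution and are
#' clamped at `mean(b) +/- clamp` with `edge = TRUE`.
#'
#' @param y binary response vector for one test.
#' @param b difficulty vector (same length).
#' @param clamp logit clamp for perfect/zero scores (default 8).
#' @return List with `theta` (estimate) and `edge` (logical flag).
#' @examples
#' raw_score(c(1, 1, 0), c(-1, 0, 1))
#' @export
raw_score <- function(y, b, clamp = 8) {
  if (length(y) == 0 || length(y) != length(b))
    stop("y and b must be nonempty vectors of equal length")
  if (!all(y %in% c(0, 1))) stop("y must be binary")
  k <- sum(y)
  if (k == 0 || k == length(y))
    return(list(theta = mean(b) + if (k == 0) -clamp else clamp, edge = TRUE))
  g <- function(th) sum(plogis(th - b)) - k
  lo <- min(b) - 50
  hi <- max(b) + 50
  list(theta = uniroot(g, c(lo, hi), tol = 1e-10)$root, edge = FALSE)
}
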