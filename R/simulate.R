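## Synthetic-data generator: simulates the full joint model forward and
## retains every latent quantity for recovery and coverage testing.

#' Generating parameter values for a simulation
#'
#' Per-person truth vectors recycle to `n_persons`. The packaged defaults
#' emulate the structure of the motivating platform data on the logit
#' scale: initial abilities spread over 0.5-3.4 logits, positive growth of
#' 0.01-0.05 logits per effective day (far below the maturity ceiling, so
#' growth damping is mild), ability innovation sd 0.1 per root-day, test
#' targets drawn within +-2 logits of current ability (adaptive
#' targeting), log response times around e^6 ~ 400 seconds, and a negative
#' inverted-U slope (-0.35) so that tests matching a person's ability take
#' the longest and badly mismatched tests run several times faster.
#'
#' @param n_persons number of persons.
#' @param theta0 true initial abilities.
#' @param beta true growth rates (>= 0).
#' @param gamma true person mean log times.
#' @param lam_delta,lam_e,lam_tau true per-person precisions of the daily,
#'   test and speed random effects.
#' @param rho true linkage slope.
#' @param lam_theta true innovation precision of the ability process.
#' @param lam_eps true residual precision of the log times.
#' @param d_offset half-width of the uniform offset of the test target
#'   difficulty around current true ability (the adaptive-design rule
#'   `d = theta + U(-d_offset, d_offset)`).
#' @return A `sim_truth` parameter list.
#' @export
sim_truth <- function(n_persons = 10,
                      theta0 = c(0.5, 0.8, 1.2, 1.5, 1.8, 2.0, 2.3, 2.6,
                                 3.0, 3.4),
                      beta = c(0.030, 0.045, 0.015, 0.035, 0.050, 0.020,
                               0.040, 0.030, 0.012, 0.048),
                      gamma = c(6.2, 5.8, 6.5, 6.0, 6.8, 5.6, 6.3, 6.1,
                                6.6, 5.9),
                      lam_delta = c(8, 12, 10, 9, 11, 10, 7, 13, 10, 9),
                      lam_e = c(10, 9, 11, 12, 8, 10, 13, 9, 10, 11),
                      lam_tau = c(25, 30, 20, 28, 22, 26, 24, 32, 18, 27),
                      rho = -0.35, lam_theta = 100, lam_eps = 25,
                      d_offset = 2) {
  rec <- function(x) rep(x, length.out = n_persons)
  tr <- list(n_persons = as.integer(n_persons), theta0 = rec(theta0),
             beta = rec(beta), gamma = rec(gamma),
             lam_delta = rec(lam_delta), lam_e = rec(lam_e),
             lam_tau = rec(lam_tau), rho = rho, lam_theta = lam_theta,
             lam_eps = lam_eps, d_offset = d_offset)
  for (nm in c("lam_delta", "lam_e", "lam_tau")) {
    if (any(tr[[nm]] <= 0)) stop("truth parameter ", nm, " must be positive")
  }
  if (lam_theta <= 0 || lam_eps <= 0)
    stop("truth precisions must be positive")
  if (any(tr$beta < 0)) stop("truth growth rates must be nonnegative")
  structure(tr, class = "sim_truth")
}

#' Simulate a DIR-RT dataset
#'
#' Simulates ability paths from the system equation, sets each test's
#' target difficulty to the person's current true ability plus a uniform
#' offset (emulating adaptive test selection), draws item difficulties
#' around the target, then generates item responses from the logistic
#' observation equation and response times from the lognormal observation
#' equation with the chosen linkage. Deterministic given the seed.
#'
#' @param design a [dirt_design].
#' @param truth a [sim_truth]; must have `n_persons` matching the design.
#' @param kind linkage kind, `"monotone"` or `"inverted_u"`.
#' @param seed integer RNG seed.
#' @return List with `data` (a [dirt_data]) and `truth` (a
#'   `simulation_truth` carrying the generating parameters, all latent
#'   paths and effects, the design, linkage and seed).
#' @export
simulate_dataset <- function(design, truth = sim_truth(design$n_persons),
                             kind = "inverted_u", seed = 1) {
  kind <- match_linkage(kind)
  stopifnot(inherits(design, "dirt_design"))
  if (truth$n_persons != design$n_persons)
    stop("truth is for ", truth$n_persons, " persons but design has ",
         design$n_persons)
  for (nm in c("theta0", "beta", "gamma", "lam_delta", "lam_e", "lam_tau",
               "rho", "lam_theta", "lam_eps", "d_offset")) {
    if (is.null(truth[[nm]])) stop("truth is missing parameter ", nm)
  }
  set.seed(as.integer(seed))
  np <- design$n_persons
  Tn <- design$n_dates
  S <- design$tests_per_day
  L <- design$items_per_test

  resp <- vector("list", np)
  tms <- vector("list", np)
  theta_path <- matrix(NA_real_, np, Tn)
  delta_all <- matrix(NA_real_, np, Tn)
  tau_all <- matrix(NA_real_, np, Tn)
  e_all <- array(NA_real_, c(np, Tn, S))
  b_all <- vector("list", np)

  for (i in seq_len(np)) {
    th <- numeric(Tn)
    th[1] <- truth$theta0[i]
    if (Tn > 1) {
      for (t in 2:Tn) {
        tr <- ability_transition(th[t - 1], truth$beta[i],
                                 design$lapses[[i]][t - 1], design$h_max,
                                 design$theta_M, truth$lam_theta)
        th[t] <- rnorm(1, tr$mean, sqrt(tr$variance))
      }
    }
    theta_path[i, ] <- th

    delta <- rnorm(Tn, 0, sqrt(1 / truth$lam_delta[i]))
    tau <- rnorm(Tn, 0, sqrt(1 / truth$lam_tau[i]))
    delta_all[i, ] <- delta
    tau_all[i, ] <- tau

    rr <- vector("list", Tn)
    tt <- vector("list", Tn)
    bb <- vector("list", Tn)
    for (t in seq_len(Tn)) {
      eps <- rnorm(S, 0, sqrt(1 / truth$lam_e[i]))
      e <- if (S == 1) 0 else eps - mean(eps)   # exact singular normal
      e_all[i, t, ] <- e
      d <- th[t] + runif(S, -truth$d_offset, truth$d_offset)
      b <- matrix(rnorm(S * L, rep(d, each = L), design$sigma_b), L, S)
      bb[[t]] <- b
      prob <- plogis(th[t] - b + delta[t] + rep(e, each = L))
      yy <- matrix(as.integer(runif(S * L) < prob), L, S)
      rr[[t]] <- data.frame(person = i, day = t,
                            test = rep(seq_len(S), each = L),
                            item = rep(seq_len(L), S),
                            y = as.vector(yy),
                            d = rep(d, each = L))
      f <- linkage_value(kind, th[t], d)
      mu <- log_rt_mean(truth$gamma[i], tau[t], truth$rho, f)
      tt[[t]] <- data.frame(person = i, day = t, test = seq_len(S),
                            seconds = exp(rnorm(S, mu,
                                                sqrt(1 / truth$lam_eps))))
    }
    resp[[i]] <- do.call(rbind, rr)
    tms[[i]] <- do.call(rbind, tt)
    b_all[[i]] <- bb
  }

  data <- dirt_data(do.call(rbind, resp), do.call(rbind, tms), design)
  truth_out <- structure(c(unclass(truth),
                           list(theta = theta_path, delta = delta_all,
                                tau = tau_all, e = e_all, b = b_all,
                                design = design, kind = kind,
                                seed = as.integer(seed))),
                         class = "simulation_truth")
  list(data = data, truth = truth_out)
}
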