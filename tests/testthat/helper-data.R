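# shared fixtures, built in code

# the acceptance coverage experiment is shared by two criteria blocks;
# memoise it so the suite runs it once
.acc_cache <- new.env(parent = emptyenv())
acceptance_coverage <- function() {
  if (is.null(.acc_cache$cv)) {
    .acc_cache$cv <- coverage_experiment(
      default_design(persons = 10, dates = 15, tests = 2, items = 5),
      sim_truth(10), "inverted_u", n_reps = 10,
      cfg = dirt_mcmc(n_iter = 3000, burn_in = 1500), seed = 2026)
  }
  .acc_cache$cv
}

tiny_design <- function(persons = 2, dates = 3, tests = 2, items = 2, ...) {
  default_design(persons = persons, dates = dates, tests = tests,
                 items = items, ...)
}

tiny_sim <- function(persons = 2, dates = 3, tests = 2, items = 2,
                     kind = "inverted_u", seed = 1,
                     truth = sim_truth(persons), ...) {
  simulate_dataset(tiny_design(persons, dates, tests, items, ...),
                   truth, kind, seed = seed)
}

# random small state consistent with a dataset, for log-likelihood oracles
random_state <- function(dataset) {
  fl <- dirt:::flatten_data(dataset)
  e <- rnorm(fl$n_tests)
  for (cc in seq_len(fl$n_cells)) {
    sel <- fl$test_cell == cc
    e[sel] <- if (sum(sel) == 1) 0 else e[sel] - mean(e[sel])
  }
  list(theta = rnorm(fl$n_cells, 1.5, 0.8),
       b = rnorm(fl$n_items, fl$d[fl$item_test], 0.5),
       delta = rnorm(fl$n_cells, 0, 0.3),
       e = e,
       tau = rnorm(fl$n_cells, 0, 0.2),
       beta = runif(fl$n_persons, 0, 3),
       gamma = rnorm(fl$n_persons, 6, 0.5),
       rho = rnorm(1, 0, 0.5),
       lam_delta = runif(fl$n_persons, 5, 15),
       lam_e = runif(fl$n_persons, 5, 15),
       lam_tau = runif(fl$n_persons, 10, 30),
       lam_theta = runif(1, 0.5, 2),
       lam_eps = runif(1, 10, 30))
}

# term-by-term complete-data log-likelihood, written independently of the
# package implementation (naive loops over long-format rows)
loglik_oracle <- function(dataset, st, kind) {
  fl <- dirt:::flatten_data(dataset)
  ll <- 0
  for (k in seq_len(fl$n_items)) {
    tt <- fl$item_test[k]; cc <- fl$test_cell[tt]
    eta <- st$theta[cc] - st$b[k] + st$delta[cc] + st$e[tt]
    p <- 1 / (1 + exp(-eta))
    ll <- ll + log(ifelse(fl$y[k] == 1, p, 1 - p))
    ll <- ll + dnorm(st$b[k], fl$d[tt], fl$sigma_b, log = TRUE)
  }
  if (fl$has_times) {
    for (tt in seq_len(fl$n_tests)) {
      cc <- fl$test_cell[tt]; p <- fl$cell_person[cc]
      x <- st$theta[cc] - fl$d[tt]
      f <- if (kind == "monotone") x else x^2
      mu <- st$gamma[p] - st$tau[cc] + st$rho * f
      ll <- ll + dnorm(fl$logT[tt], mu, 1 / sqrt(st$lam_eps), log = TRUE)
    }
    for (cc in seq_len(fl$n_cells)) {
      ll <- ll + dnorm(st$tau[cc], 0,
                       1 / sqrt(st$lam_tau[fl$cell_person[cc]]), log = TRUE)
    }
  }
  for (cc in seq_len(fl$n_cells)) {
    p <- fl$cell_person[cc]
    ll <- ll + dnorm(st$delta[cc], 0, 1 / sqrt(st$lam_delta[p]), log = TRUE)
    es <- st$e[fl$test_cell == cc]
    S <- length(es)
    if (S > 1) {
      ll <- ll + 0.5 * (S - 1) * log(st$lam_e[p] / (2 * pi)) -
        0.5 * st$lam_e[p] * sum(es^2)
    }
    if (cc > 1 && fl$cell_person[cc - 1] == p) {
      h <- fl$cell_lapse[cc]
      m <- st$theta[cc - 1] + st$beta[p] * h *
        (1 - st$theta[cc - 1] / fl$theta_M)
      ll <- ll + dnorm(st$theta[cc], m, sqrt(h / st$lam_theta), log = TRUE)
    }
  }
  ll
}

# dense joint-Gaussian solve of the state-space conditional, used as the
# independent oracle for the FFBS smoother
dense_state_oracle <- function(cc, aa, qq, P, W, mu0, v0) {
  T <- length(P)
  Q <- matrix(0, T, T); h <- numeric(T)
  Q[1, 1] <- 1 / v0; h[1] <- mu0 / v0
  if (T > 1) {
    for (t in 2:T) {
      Q[t, t] <- Q[t, t] + 1 / qq[t]
      Q[t - 1, t - 1] <- Q[t - 1, t - 1] + cc[t]^2 / qq[t]
      Q[t - 1, t] <- Q[t, t - 1] <- Q[t - 1, t] - cc[t] / qq[t]
      h[t] <- h[t] + aa[t] / qq[t]
      h[t - 1] <- h[t - 1] - cc[t] * aa[t] / qq[t]
    }
  }
  diag(Q) <- diag(Q) + P
  h <- h + W
  V <- solve(Q)
  list(mean = as.vector(V %*% h), var = diag(V),
       lag1 = if (T > 1) V[cbind(1:(T - 1), 2:T)] else numeric(0))
}
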