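test_that("FFBS conditional moments match a dense joint-Gaussian solve", {
  set.seed(21)
  for (rep in 1:25) {
    T <- sample(2:9, 1)
    cc <- c(0, runif(T - 1, 0.7, 1.05))
    aa <- c(0, runif(T - 1, -1, 3))
    qq <- c(1, runif(T - 1, 0.05, 3))
    P <- runif(T, 0, 5) * rbinom(T, 1, 0.8)  # some dates unobserved
    W <- P * rnorm(T, 2, 1)
    mu0 <- rnorm(1, 2, 1); v0 <- runif(1, 0.5, 4)
    ff <- dirt:::cpp_ffbs_moments(cc, aa, qq, P, W, mu0, v0)
    or <- dense_state_oracle(cc, aa, qq, P, W, mu0, v0)
    expect_lt(max(abs(ff$mean - or$mean)), 1e-8)
    expect_lt(max(abs(ff$var - or$var)), 1e-8)
    expect_lt(max(abs(ff$lag1cov - or$lag1)), 1e-8)
  }
})

test_that("unobserved dates are smoothed with wider uncertainty", {
  T <- 5
  cc <- c(0, rep(1, T - 1)); aa <- c(0, rep(0, T - 1))
  qq <- c(1, rep(0.5, T - 1))
  P <- c(4, 4, 0, 4, 4)           # no observations on date 3
  W <- P * 2
  mm <- dirt:::cpp_ffbs_moments(cc, aa, qq, P, W, 2, 10)
  expect_gt(mm$var[3], max(mm$var[c(2, 4)]))
  # interpolates between neighbours
  expect_lt(abs(mm$mean[3] - mean(mm$mean[c(2, 4)])), 0.1)
})

test_that("chains are bit-reproducible under a fixed seed", {
  sim <- tiny_sim(seed = 3)
  cfg <- dirt_mcmc(n_iter = 120, burn_in = 40, seed = 5)
  f1 <- run_chain(sim$data, dirt_priors(), cfg)
  f2 <- run_chain(sim$data, dirt_priors(), cfg)
  expect_identical(f1$draws, f2$draws)
  f3 <- run_chain(sim$data, dirt_priors(),
                  dirt_mcmc(n_iter = 120, burn_in = 40, seed = 6))
  expect_false(identical(f1$draws$rho, f3$draws$rho))
})

test_that("test effects satisfy the sum-to-zero constraint at every sweep", {
  sim <- tiny_sim(persons = 3, dates = 4, tests = 3, items = 3, seed = 9)
  fit <- run_chain(sim$data, dirt_priors(),
                   dirt_mcmc(n_iter = 200, burn_in = 50, seed = 2,
                             store_latent = TRUE))
  expect_lt(max(fit$e_maxsum), 1e-12)
  fl <- dirt:::flatten_data(sim$data)
  for (cc in seq_len(fl$n_cells)) {
    sums <- rowSums(fit$draws$e[, fl$test_cell == cc, drop = FALSE])
    expect_lt(max(abs(sums)), 1e-12)
  }
  # precisions positive at every retained draw
  expect_true(all(fit$draws$lam_delta > 0) && all(fit$draws$lam_e > 0) &&
                all(fit$draws$lam_tau > 0) && all(fit$draws$lam_theta > 0) &&
                all(fit$draws$lam_eps > 0))
})

test_that("single day with one test gives a zero test effect", {
  sim <- tiny_sim(persons = 2, dates = 3, tests = 1, items = 4, seed = 4)
  fit <- run_chain(sim$data, dirt_priors(),
                   dirt_mcmc(n_iter = 100, burn_in = 20, seed = 1,
                             store_latent = TRUE))
  expect_true(all(fit$draws$e == 0))
})

test_that("single-site inverted-U sampler matches the grid-normalised density", {
  # known quartic-exponent conditional
  m0 <- 1; v0 <- 0.25; rho <- -0.6; lam_eps <- 25
  r <- c(-0.3, 0.1); d <- c(0.8, 1.5)
  set.seed(77)
  draws <- dirt:::cpp_theta_invu_draws(1e6, m0, v0, rho, lam_eps, r, d,
                                       301, 8)
  # independent fine-grid normalisation of the same density
  grid <- seq(m0 - 8 * sqrt(v0), m0 + 8 * sqrt(v0), length.out = 4001)
  ld <- -0.5 * (grid - m0)^2 / v0
  for (s in 1:2) ld <- ld - 0.5 * lam_eps * (r[s] - rho * (grid - d[s])^2)^2
  dens <- exp(ld - max(ld)); dens <- dens / sum(dens)
  # compare on 60 coarse bins
  edges <- seq(min(grid), max(grid), length.out = 61)
  p_grid <- tapply(dens, cut(grid, edges, include.lowest = TRUE), sum)
  p_draw <- tabulate(cut(draws, edges, include.lowest = TRUE, labels = FALSE),
                     nbins = 60) / length(draws)
  tv <- 0.5 * sum(abs(p_grid - p_draw), na.rm = TRUE)
  expect_lt(tv, 0.01)
})

test_that("single-site sampler reduces to the Gaussian when the slope is zero", {
  set.seed(78)
  draws <- dirt:::cpp_theta_invu_draws(1e4, 2, 0.49, 0, 25, c(0.5, -0.5),
                                       c(1, 3), 301, 8)
  ks <- suppressWarnings(stats::ks.test(draws, pnorm, mean = 2, sd = 0.7))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("conjugate item-difficulty update matches the normal-normal algebra", {
  sim <- tiny_sim(persons = 1, dates = 1, tests = 1, items = 1, seed = 6)
  fl <- dirt:::flatten_data(sim$data)
  dat <- dirt:::flat_for_cpp(fl)
  pri <- unclass(dirt_priors())
  st <- dirt:::init_state(fl)
  st$theta <- 0.8; st$delta <- 0.2; st$e <- 0; st$z <- 0.4; st$psi <- 0.6
  # closed-form conditional
  u <- st$theta + st$delta + st$e - st$z
  prec <- 1 / fl$sigma_b^2 + 1 / (4 * st$psi^2)
  m_exp <- (fl$d / fl$sigma_b^2 + u / (4 * st$psi^2)) / prec
  set.seed(10)
  bs <- replicate(6000, dirt:::cpp_sweep(dat, st, pri, 1L, 3L)$b)
  expect_lt(abs(mean(bs) - m_exp), 4 * sqrt(1 / prec) / sqrt(6000))
  expect_lt(abs(sd(bs) - sqrt(1 / prec)), 0.05 * sqrt(1 / prec))
  # sigma_b -> 0 pins b at the target difficulty
  sim2 <- tiny_sim(persons = 1, dates = 1, tests = 1, items = 1, seed = 6,
                   sigma_b = 1e-6)
  fl2 <- dirt:::flatten_data(sim2$data)
  st2 <- dirt:::init_state(fl2)
  b2 <- dirt:::cpp_sweep(dirt:::flat_for_cpp(fl2), st2, pri, 1L, 3L)$b
  expect_lt(abs(b2 - fl2$d), 1e-4)
  # huge psi (no likelihood information) falls back to the prior
  st$psi <- 1e6
  set.seed(11)
  bs <- replicate(6000, dirt:::cpp_sweep(dat, st, pri, 1L, 3L)$b)
  expect_lt(abs(mean(bs) - fl$d), 4 * fl$sigma_b / sqrt(6000))
  expect_lt(abs(sd(bs) - fl$sigma_b), 0.05 * fl$sigma_b)
})

test_that("constrained test-effect update matches the reduced univariate normal", {
  sim <- tiny_sim(persons = 1, dates = 1, tests = 2, items = 2, seed = 8)
  fl <- dirt:::flatten_data(sim$data)
  dat <- dirt:::flat_for_cpp(fl)
  pri <- unclass(dirt_priors())
  st <- dirt:::init_state(fl)
  st$theta <- 1; st$delta <- 0.1
  st$z <- c(0.7, -0.2, 0.3, 0.9); st$psi <- c(0.4, 0.7, 0.5, 0.6)
  st$lam_e <- 10
  # closed form: substitute e2 = -e1 into the two tests' Gaussian terms
  pl <- 1 / (4 * st$psi^2)
  w <- st$z + st$b - st$theta - st$delta
  prec_s <- st$lam_e + c(sum(pl[1:2]), sum(pl[3:4]))
  wsum_s <- c(sum((pl * w)[1:2]), sum((pl * w)[3:4]))
  m_s <- wsum_s / prec_s; v_s <- 1 / prec_s
  prec1 <- 1 / v_s[1] + 1 / v_s[2]
  mean1 <- (m_s[1] / v_s[1] - m_s[2] / v_s[2]) / prec1
  set.seed(12)
  es <- t(replicate(6000, dirt:::cpp_sweep(dat, st, pri, 1L, 5L)$e))
  expect_lt(max(abs(rowSums(es))), 1e-12)
  expect_lt(abs(mean(es[, 1]) - mean1), 4 / sqrt(prec1) / sqrt(6000))
  expect_lt(abs(sd(es[, 1]) - sqrt(1 / prec1)), 0.05 / sqrt(prec1))
})

test_that("daily-effect update matches its Gaussian conditional", {
  sim <- tiny_sim(persons = 1, dates = 1, tests = 1, items = 3, seed = 14)
  fl <- dirt:::flatten_data(sim$data)
  dat <- dirt:::flat_for_cpp(fl)
  pri <- unclass(dirt_priors())
  st <- dirt:::init_state(fl)
  st$theta <- 0.5; st$e <- 0
  st$z <- c(0.2, -0.4, 0.8); st$psi <- c(0.5, 0.45, 0.7)
  st$lam_delta <- 9
  pl <- 1 / (4 * st$psi^2)
  v <- st$z + st$b - st$theta - st$e
  prec <- st$lam_delta + sum(pl)
  m_exp <- sum(pl * v) / prec
  set.seed(15)
  ds <- replicate(6000, dirt:::cpp_sweep(dat, st, pri, 1L, 4L)$delta)
  expect_lt(abs(mean(ds) - m_exp), 4 / sqrt(prec) / sqrt(6000))
  expect_lt(abs(sd(ds) - 1 / sqrt(prec)), 0.05 / sqrt(prec))
})

test_that("growth-rate update is nonnegative and concentrates on noiseless data", {
  sim <- tiny_sim(persons = 1, dates = 6, tests = 1, items = 2, seed = 16)
  fl <- dirt:::flatten_data(sim$data)
  dat <- dirt:::flat_for_cpp(fl)
  pri <- unclass(dirt_priors())
  st <- dirt:::init_state(fl)
  # theta path generated exactly by beta* = 0.5 with no noise
  beta_star <- 0.5
  th <- numeric(fl$n_cells); th[1] <- 1
  for (t in 2:fl$n_cells) {
    th[t] <- th[t - 1] + beta_star * fl$cell_lapse[t] *
      (1 - th[t - 1] / fl$theta_M)
  }
  st$theta <- th
  st$lam_theta <- 1e8
  set.seed(17)
  bs <- replicate(2000, dirt:::cpp_sweep(dat, st, pri, 1L, 7L)$beta)
  expect_true(all(bs >= 0))
  expect_lt(abs(mean(bs) - beta_star), 1e-3)
  # conditional mass below zero piles draws near the boundary
  th_dec <- seq(2, 1, length.out = fl$n_cells)
  st$theta <- th_dec; st$lam_theta <- 100
  bs <- replicate(2000, dirt:::cpp_sweep(dat, st, pri, 1L, 7L)$beta)
  expect_true(all(bs >= 0) && mean(bs) < 0.05)
})

test_that("time-block conditionals recover their regression identities", {
  sim <- tiny_sim(persons = 1, dates = 8, tests = 2, items = 2, seed = 18)
  fl <- dirt:::flatten_data(sim$data)
  dat <- dirt:::flat_for_cpp(fl)
  pri <- unclass(dirt_priors())
  st <- dirt:::init_state(fl)
  st$tau <- rep(0, fl$n_cells)
  # single observation with flat prior: gamma conditional centres on the
  # adjusted log-time
  sim1 <- tiny_sim(persons = 1, dates = 1, tests = 1, items = 2, seed = 19)
  fl1 <- dirt:::flatten_data(sim1$data)
  st1 <- dirt:::init_state(fl1)
  st1$tau <- 0.3; st1$rho <- -0.2; st1$theta <- 1.4
  st1$lam_eps <- 1e8; st1$lam_tau <- 1e8
  f1 <- (st1$theta - fl1$d)^2
  g <- dirt:::cpp_sweep(dirt:::flat_for_cpp(fl1), st1, pri, 1L, 8L)$gamma
  expect_lt(abs(g - (fl1$logT + st1$tau - st1$rho * f1)), 1e-3)
  # tau has zero mean across a day-rich person (identifiability)
  st$lam_eps <- 25; st$lam_tau <- 25
  set.seed(20)
  taus <- replicate(400, mean(dirt:::cpp_sweep(dat, st, pri, 1L, 8L)$tau))
  expect_lt(abs(mean(taus)), 0.05)
})

test_that("precision updates follow the Gamma sufficient-statistic identity", {
  sim <- tiny_sim(persons = 1, dates = 5, tests = 1, items = 2, seed = 22)
  fl <- dirt:::flatten_data(sim$data)
  dat <- dirt:::flat_for_cpp(fl)
  pri <- unclass(dirt_priors(a_delta = 2, b_delta = 3))
  st <- dirt:::init_state(fl)
  st$delta <- rep(0, fl$n_cells)  # all-zero residuals
  set.seed(23)
  ld <- replicate(6000, dirt:::cpp_sweep(dat, st, pri, 1L, 9L)$lam_delta)
  # conditional is Gamma(a + T/2, b) when all residuals vanish
  sh <- 2 + fl$n_cells / 2
  expect_lt(abs(mean(ld) - sh / 3), 4 * sqrt(sh) / 3 / sqrt(6000))
  expect_true(all(ld > 0))
  # lam_eps conditional mean approaches 1/Var(resid) as n grows
  sim2 <- tiny_sim(persons = 2, dates = 40, tests = 2, items = 1, seed = 24)
  fl2 <- dirt:::flatten_data(sim2$data)
  st2 <- dirt:::init_state(fl2)
  st2$theta <- as.vector(t(sim2$truth$theta))
  st2$tau <- as.vector(t(sim2$truth$tau))
  st2$gamma <- sim2$truth$gamma
  st2$rho <- sim2$truth$rho
  set.seed(25)
  le <- replicate(400, dirt:::cpp_sweep(dirt:::flat_for_cpp(fl2), st2,
                                        unclass(dirt_priors()), 1L, 9L)$lam_eps)
  expect_lt(abs(mean(le) / sim2$truth$lam_eps - 1), 0.35)
})

test_that("a degenerate one-date fit matches a direct grid posterior", {
  # one person, one date, one test: random effects and nuisance scales are
  # pinned by near-degenerate priors so the ability posterior is exactly
  # prior x logistic-likelihood x time-likelihood, integrable on a grid
  th_star <- 1.2; d0 <- 1.5; gam0 <- 6; rho0 <- -0.35
  lam_eps0 <- 25
  set.seed(30)
  L <- 8
  y <- as.integer(runif(L) < plogis(th_star - d0))
  logT0 <- rnorm(1, gam0 + rho0 * (th_star - d0)^2, sqrt(1 / lam_eps0))
  resp <- data.frame(person = 1, day = 1, test = 1, item = 1:L, y = y,
                     d = d0)
  tms <- data.frame(person = 1, day = 1, test = 1, seconds = exp(logT0))
  des <- dirt_design(1, 1, 1, L, lapses = numeric(0), sigma_b = 1e-5,
                     subpop_mu = 1, subpop_sd = 1)
  dat <- dirt_data(resp, tms, des)
  pri <- dirt_priors(a_delta = 1e12, b_delta = 1e6, a_e = 1e12, b_e = 1e6,
                     a_tau = 1e12, b_tau = 1e6,
                     a_eps = 1e8 * lam_eps0, b_eps = 1e8,
                     gamma_mean = gam0, gamma_prec = 1e12,
                     rho_mean = rho0, rho_prec = 1e12)
  fit <- run_chain(dat, pri, dirt_mcmc(n_iter = 24000, burn_in = 4000,
                                       seed = 31))
  grid <- seq(-3, 5, by = 0.002)
  k <- sum(y)
  lp <- dnorm(grid, 1, 1, log = TRUE) +
    k * plogis(grid - d0, log.p = TRUE) +
    (L - k) * plogis(-(grid - d0), log.p = TRUE) +
    dnorm(logT0, gam0 + rho0 * (grid - d0)^2, sqrt(1 / lam_eps0),
          log = TRUE)
  w <- exp(lp - max(lp)); w <- w / sum(w)
  m_grid <- sum(grid * w)
  s_grid <- sqrt(sum((grid - m_grid)^2 * w))
  th_draws <- fit$draws$theta[, 1]
  expect_lt(abs(mean(th_draws) - m_grid), 0.03)
  expect_lt(abs(sd(th_draws) - s_grid), 0.03)
})

test_that("with a null slope, DIR and DIR-RT agree on the ability posterior", {
  tr0 <- sim_truth(3, rho = 0)
  sim <- simulate_dataset(default_design(3, 8, 2, 4), tr0, "monotone",
                          seed = 33)
  cfg <- dirt_mcmc(n_iter = 8000, burn_in = 4000, seed = 34,
                   linkage = "monotone")
  fit_rt <- run_chain(sim$data, dirt_priors(), cfg)
  fit_dir <- run_chain(make_dir_only_view(sim$data), dirt_priors(), cfg)
  m_rt <- colMeans(fit_rt$draws$theta)
  m_dir <- colMeans(fit_dir$draws$theta)
  # time data carry no ability information at rho = 0: posterior means
  # agree up to the two chains' Monte-Carlo error, a small fraction of
  # the posterior spread
  psd <- mean(apply(fit_rt$draws$theta, 2, sd))
  expect_lt(mean(abs(m_rt - m_dir)) / psd, 0.15)
  expect_gt(cor(m_rt, m_dir), 0.98)
})
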