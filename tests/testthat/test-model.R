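test_that("logistic response probability matches the logistic cdf and its symmetry", {
  expect_equal(logistic_response_prob(0, 0), 0.5)
  expect_equal(logistic_response_prob(1.0, 0.5), 1 / (1 + exp(-0.5)),
               tolerance = 1e-12)
  expect_equal(logistic_response_prob(1.0, 0.5), 0.6224593, tolerance = 1e-6)
  # monotone approach to 1 as ability grows
  p <- logistic_response_prob(c(1, 5, 20, 50), 0)
  expect_true(all(diff(p) > 0) && p[4] > 1 - 1e-12)
  # increasing in theta, decreasing in b
  expect_gt(logistic_response_prob(1, 0), logistic_response_prob(0.5, 0))
  expect_lt(logistic_response_prob(0, 1), logistic_response_prob(0, 0.5))
  # symmetry property over random inputs
  set.seed(1)
  for (i in 1:100) {
    x <- rnorm(4, 0, 2)
    expect_equal(logistic_response_prob(x[1], x[2], x[3], x[4]) +
                   logistic_response_prob(-x[1], -x[2], -x[3], -x[4]), 1,
                 tolerance = 1e-12)
  }
  expect_error(logistic_response_prob(Inf, 0), "non-finite")
})

test_that("linkage functions are linear / quadratic in the signed distance", {
  expect_equal(linkage_value("inverted_u", 3, 3), 0)
  expect_equal(linkage_value("monotone", 3.7, 3), 0.7, tolerance = 1e-12)
  set.seed(2)
  for (cst in rnorm(20, 0, 2)) {
    expect_equal(linkage_value("inverted_u", 5 + cst, 5),
                 linkage_value("inverted_u", 5 - cst, 5), tolerance = 1e-12)
  }
  # linearity of the monotone form (the dynamic-linear-model requirement)
  th <- rnorm(10); d <- 0.3
  f <- linkage_value("monotone", th, d)
  expect_equal(f, th - d, tolerance = 1e-12)
  expect_error(linkage_value("bent", 0, 0), "kind")
})

test_that("log response-time mean combines speed and linkage correctly", {
  expect_equal(log_rt_mean(3, 0, 0, 99), 3)
  expect_equal(log_rt_mean(3.0, 0.2, 0, 5), 2.8)
  expect_equal(log_rt_mean(3.0, 0.0, -0.1, 4.0), 2.6)
})

test_that("ability transition has the stated moments and is linear in theta_prev", {
  # growth stalls at maturity
  tr <- ability_transition(1000, 2, 3, 30, 1000, 4)
  expect_equal(tr$mean, 1000)
  # pure random walk when beta = 0
  tr <- ability_transition(420, 0, 7, 30, 1000, 2)
  expect_equal(tr$mean, 420)
  expect_equal(tr$variance, 7 / 2)
  # arithmetic example
  tr <- ability_transition(500, 1, 10, 30, 1000, 4)
  expect_equal(tr$mean, 505)
  expect_equal(tr$variance, 2.5)
  # lapse capping
  tr <- ability_transition(500, 1, 100, 30, 1000, 4)
  expect_equal(tr$variance, 30 / 4)
  # exact linearity with slope 1 - beta h / theta_M
  h <- 4; beta <- 1.5; thM <- 1000
  m1 <- ability_transition(300, beta, h, 30, thM, 1)$mean
  m2 <- ability_transition(301, beta, h, 30, thM, 1)$mean
  expect_equal(m2 - m1, 1 - beta * h / thM, tolerance = 1e-12)
  expect_error(ability_transition(1, 1, 1, 0, 1000, 1), "cap")
  expect_error(ability_transition(1, 1, 1, 30, 0, 1), "theta_M")
})

test_that("complete log-likelihood matches an independent term-by-term oracle", {
  set.seed(31)
  for (i in 1:60) {
    sim <- tiny_sim(persons = sample(1:2, 1), dates = sample(2:3, 1),
                    tests = sample(1:3, 1), items = 2, seed = i)
    st <- random_state(sim$data)
    kind <- sample(c("monotone", "inverted_u"), 1)
    expect_equal(complete_loglik(sim$data, st, kind),
                 loglik_oracle(sim$data, st, kind), tolerance = 1e-10)
  }
  # DIR datasets drop the time terms
  sim <- tiny_sim(seed = 99)
  dir_dat <- make_dir_only_view(sim$data)
  st <- random_state(sim$data)
  expect_equal(complete_loglik(dir_dat, st, "inverted_u"),
               loglik_oracle(dir_dat, st, "inverted_u"), tolerance = 1e-10)
})

test_that("doubling the time precision changes only the Gaussian scale term", {
  sim <- tiny_sim(seed = 5)
  st <- random_state(sim$data)
  st2 <- st
  st2$lam_eps <- 2 * st$lam_eps
  fl <- dirt:::flatten_data(sim$data)
  # analytic difference: n/2 log 2 - (lam_eps/2) * sum(resid^2)
  tc <- fl$test_cell; tp <- fl$cell_person[tc]
  f <- linkage_value("inverted_u", st$theta[tc], fl$d)
  resid <- fl$logT - (st$gamma[tp] - st$tau[tc] + st$rho * f)
  expected <- 0.5 * fl$n_tests * log(2) - 0.5 * st$lam_eps * sum(resid^2)
  expect_equal(complete_loglik(sim$data, st2, "inverted_u") -
                 complete_loglik(sim$data, st, "inverted_u"),
               expected, tolerance = 1e-8)
})

test_that("raw score solves the expected-score equation", {
  # equal difficulties reduce to b0 + log(k / (L - k))
  rs <- raw_score(c(rep(1, 7), rep(0, 3)), rep(0, 10))
  expect_equal(rs$theta, log(7 / 3), tolerance = 1e-8)
  expect_equal(rs$theta, 0.8473, tolerance = 1e-4)
  expect_false(rs$edge)
  rs <- raw_score(c(rep(1, 7), rep(0, 3)), rep(1.5, 10))
  expect_equal(rs$theta, 1.5 + log(7 / 3), tolerance = 1e-8)
  # perfect score clamps with a flag
  rs <- raw_score(c(1, 1, 1), c(-1, 0, 1))
  expect_true(rs$edge)
  expect_equal(rs$theta, 0 + 8)
  rs0 <- raw_score(c(0, 0, 0), c(-1, 0, 1))
  expect_true(rs0$edge && rs0$theta == -8)
  # bisection oracle for unequal difficulties
  b <- c(-1, 0, 1); y <- c(1, 1, 0)
  g <- function(th) sum(plogis(th - b)) - 2
  lo <- -20; hi <- 20
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
  }
  expect_equal(raw_score(y, b)$theta, (lo + hi) / 2, tolerance = 1e-8)
  # monotone nondecreasing in number correct
  b <- c(-0.5, 0, 0.3, 1)
  ests <- vapply(0:4, function(k) {
    raw_score(c(rep(1, k), rep(0, 4 - k)), b)$theta
  }, 0)
  expect_true(all(diff(ests) >= 0))
  expect_error(raw_score(numeric(0), numeric(0)), "nonempty")
})
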