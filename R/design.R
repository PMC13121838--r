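## Test-design objects: who is tested when, how many tests per day and
## items per test, plus the design constants that the platform fixes
## (difficulty dispersion sigma_b, maturity ceiling theta_M, lapse cap).

#' Construct a test design
#'
#' Describes the administration structure: each of `n_persons` persons
#' takes `tests_per_day` tests with `items_per_test` items on each of
#' `n_dates` test dates, with given inter-date time lapses. Constants known
#' from the test design ride along: the dispersion `sigma_b` of randomized
#' item difficulties around the test target, the maturity ceiling
#' `theta_M` of the growth model, the lapse cap `h_max`, and the
#' subpopulation prior for the initial ability.
#'
#' @param n_persons number of persons.
#' @param n_dates number of test dates per person.
#' @param tests_per_day tests per date.
#' @param items_per_test items per test.
#' @param lapses either a numeric vector of length `n_dates - 1` (shared by
#'   all persons), or a list of such vectors, one per person. Defaults to
#'   [default_lapses].
#' @param sigma_b known sd of item difficulties around the test target
#'   (logit scale).
#' @param theta_M maturity ceiling of the growth model (ability units,
#'   larger than any plausible ability).
#' @param h_max lapse cap in days.
#' @param subpop integer subpopulation id per person.
#' @param subpop_mu,subpop_sd initial-ability prior mean/sd per
#'   subpopulation.
#' @return A `dirt_design` list.
#' @export
dirt_design <- function(n_persons, n_dates, tests_per_day, items_per_test,
                        lapses = NULL, sigma_b = 0.4, theta_M = 1000,
                        h_max = 30, subpop = rep(1L, n_persons),
                        subpop_mu = 2, subpop_sd = 2) {
  stopifnot(n_persons >= 1, n_dates >= 1, tests_per_day >= 1,
            items_per_test >= 1, sigma_b > 0, h_max > 0, theta_M != 0,
            length(subpop) == n_persons, all(subpop_sd > 0))
  if (is.null(lapses)) lapses <- default_lapses(n_dates)
  if (!is.list(lapses)) lapses <- rep(list(lapses), n_persons)
  stopifnot(length(lapses) == n_persons)
  for (lp in lapses) {
    if (length(lp) != n_dates - 1 || any(lp <= 0))
      stop("each lapse vector must have n_dates - 1 positive entries")
  }
  structure(list(n_persons = as.integer(n_persons),
                 n_dates = as.integer(n_dates),
                 tests_per_day = as.integer(tests_per_day),
                 items_per_test = as.integer(items_per_test),
                 lapses = lapses, sigma_b = sigma_b, theta_M = theta_M,
                 h_max = h_max, subpop = as.integer(subpop),
                 subpop_mu = subpop_mu, subpop_sd = subpop_sd),
            class = "dirt_design")
}

#' Default irregular lapse pattern
#'
#' One day between consecutive test dates, except every tenth gap is five
#' days, creating the irregular spacing characteristic of the motivating
#' platform data.
#'
#' @param n_dates number of test dates.
#' @return Numeric vector of `n_dates - 1` lapses.
#' @export
default_lapses <- function(n_dates) {
  if (n_dates < 2) return(numeric(0))
  h <- rep(1, n_dates - 1)
  h[seq_along(h) %% 10 == 0] <- 5
  h
}

#' Reference simulation design
#'
#' The simulation-study administration structure: 10 persons, 50 test
#' dates, 4 tests per day, 10 items per test (20,000 responses), with the
#' default irregular lapse pattern. All dimensions scale down for
#' desk-scale runs.
#'
#' @param persons,dates,tests,items size overrides.
#' @param ... passed to [dirt_design] (e.g. `sigma_b`, `theta_M`).
#' @return A `dirt_design`.
#' @export
default_design <- function(persons = 10, dates = 50, tests = 4, items = 10,
                           ...) {
  if (persons <= 0 || dates <= 0 || tests <= 0 || items <= 0)
    stop("design size factors must be positive")
  dirt_design(persons, dates, tests, items, ...)
}

#' @export
print.dirt_design <- function(x, ...) {
  cat(sprintf(paste0("<dirt_design> %d persons x %d dates x %d tests x ",
                     "%d items (%d responses)\n"),
              x$n_persons, x$n_dates, x$tests_per_day, x$items_per_test,
              x$n_persons * x$n_dates * x$tests_per_day * x$items_per_test))
  cat(sprintf("  sigma_b = %g, theta_M = %g, h_max = %g days\n",
              x$sigma_b, x$theta_M, x$h_max))
  invisible(x)
}
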