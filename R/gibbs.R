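## Block Gibbs sampler driver. One sweep updates, in fixed order:
## augmented responses z, K-S scales psi, item difficulties b, daily
## effects delta, test effects e (sum-to-zero), ability paths theta (FFBS
## under the monotone linkage or in DIR mode; single-site grid draws under
## the inverted-U linkage), growth rates beta, the time block (gamma, tau,
## rho), and all precisions.

#' MCMC configuration
#'
#' @param n_iter total sweeps.
#' @param burn_in sweeps discarded (must be < `n_iter`; default half).
#' @param thin keep every `thin`-th post-burn-in sweep.
#' @param seed integer seed; all randomness flows through R's RNG.
#' @param linkage `"monotone"` or `"inverted_u"`.
#' @param init named list of initial values overriding the defaults
#'   (raw-score-based abilities, unit precisions, zero effects and slope,
#'   growth rate 1, person mean log-times from the data).
#' @param monitor character vector of scalar parameter groups to expose in
#'   [monitored_draws]; defaults to every scalar group the model has.
#' @param grid_n,grid_width grid resolution and half-width (in posterior
#'   sds) of the single-site inverted-U sampler.
#' @param store_latent also retain draws of `delta`, `e`, `tau`.
#' @return A `dirt_mcmc` list.
#' @export
dirt_mcmc <- function(n_iter = 4000, burn_in = floor(n_iter / 2), thin = 1,
                      seed = 1, linkage = "inverted_u", init = list(),
                      monitor = NULL, grid_n = 301, grid_width = 8,
                      store_latent = FALSE) {
  stopifnot(n_iter >= 2, burn_in >= 0, burn_in < n_iter, thin >= 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 linkage = match_linkage(linkage), init = init,
                 monitor = monitor, grid_n = as.integer(grid_n),
                 grid_width = grid_width,
                 store_latent = isTRUE(store_latent)),
            class = "dirt_mcmc")
}

## default initial values: abilities from raw scores anchored at the test
## targets, everything else neutral
init_state <- function(fl, init = list()) {
  theta <- numeric(fl$n_cells)
  for (cc in seq_len(fl$n_cells)) {
    tests <- which(fl$test_cell == cc)
    items <- fl$item_test %in% tests
    k <- sum(fl$y[items]); n <- sum(items)
    theta[cc] <- mean(fl$d[tests]) + qlogis((k + 0.5) / (n + 1))
  }
  gamma <- numeric(fl$n_persons)
  if (fl$has_times) {
    for (p in seq_len(fl$n_persons)) {
      gamma[p] <- mean(fl$logT[fl$cell_person[fl$test_cell] == p])
    }
  }
  st <- list(theta = theta,
             delta = numeric(fl$n_cells),
             tau = numeric(fl$n_cells),
             e = numeric(fl$n_tests),
             b = fl$d[fl$item_test],
             z = ifelse(fl$y == 1, 0.5, -0.5),
             psi = rep(0.5, fl$n_items),
             beta = rep(1, fl$n_persons),
             gamma = gamma,
             lam_delta = rep(1, fl$n_persons),
             lam_e = rep(1, fl$n_persons),
             lam_tau = rep(1, fl$n_persons),
             rho = 0, lam_theta = 1, lam_eps = 1)
  for (nm in names(init)) {
    if (!nm %in% names(st)) stop("unknown initial value: ", nm)
    if (length(init[[nm]]) != length(st[[nm]]) && length(init[[nm]]) != 1)
      stop("initial value ", nm, " has wrong length")
    st[[nm]] <- rep(init[[nm]], length.out = length(st[[nm]]))
  }
  st
}

#' Run the block Gibbs sampler
#'
#' Fits the DIR-RT model (or, when the dataset has no time table, the DIR
#' reduction that skips every response-time block) and returns the
#' retained posterior draws. Fully reproducible under a fixed seed.
#'
#' @param dataset a [dirt_data].
#' @param priors a [dirt_priors].
#' @param cfg a [dirt_mcmc].
#' @return A `dirt_fit` with elements `draws` (named matrices/vectors over
#'   retained sweeps), `map` (cell to person/day), `config`, `priors`,
#'   `dir_mode`, `e_maxsum` (per-sweep max |sum of test effects| within a
#'   day), and `ks_accept_rate`.
#' @export
run_chain <- function(dataset, priors = dirt_priors(), cfg = dirt_mcmc()) {
  stopifnot(inherits(dataset, "dirt_data"), inherits(priors, "dirt_priors"),
            inherits(cfg, "dirt_mcmc"))
  fl <- flatten_data(dataset)
  set.seed(cfg$seed)
  st <- init_state(fl, cfg$init)
  res <- cpp_run_chain(flat_for_cpp(fl), st, unclass(priors),
                       list(n_iter = cfg$n_iter, burn_in = cfg$burn_in,
                            thin = cfg$thin,
                            linkage = linkage_code(cfg$linkage),
                            grid_n = cfg$grid_n,
                            grid_width = cfg$grid_width,
                            store_latent = cfg$store_latent))
  draws <- list(theta = res$theta, beta = res$beta, gamma = res$gamma,
                lam_delta = res$lam_delta, lam_e = res$lam_e,
                lam_tau = res$lam_tau, rho = res$rho,
                lam_theta = res$lam_theta, lam_eps = res$lam_eps)
  if (cfg$store_latent) {
    draws$delta <- res$delta; draws$e <- res$e; draws$tau <- res$tau
  }
  structure(list(draws = draws,
                 map = data.frame(person = fl$cell_person,
                                  day = fl$cell_day),
                 n_persons = fl$n_persons,
                 dir_mode = !fl$has_times,
                 config = cfg, priors = priors,
                 e_maxsum = res$e_maxsum,
                 ks_accept_rate = res$ks_accept_rate,
                 final_state = res$final_state),
            class = "dirt_fit")
}

#' @export
print.dirt_fit <- function(x, ...) {
  cat(sprintf("<dirt_fit> %s%s, %d retained draws, %d persons\n",
              x$config$linkage, if (x$dir_mode) " (DIR reduction)" else "",
              nrow(x$draws$theta), x$n_persons))
  if (!x$dir_mode)
    cat(sprintf("  posterior median rho = %.4f\n", median(x$draws$rho)))
  invisible(x)
}

#' Monitored scalar chains
#'
#' Assembles the retained draws of the monitored scalar parameters into
#' one named matrix (columns like `beta[3]`, `rho`). The DIR reduction has
#' no time-block parameters, so `gamma`, `lam_tau`, `rho` and `lam_eps`
#' are dropped there.
#'
#' @param fit a `dirt_fit`.
#' @param monitor optional character vector of groups; defaults to the
#'   fit's configured monitor list or, failing that, every scalar group.
#' @return Matrix of retained draws, one column per monitored scalar.
#' @export
monitored_draws <- function(fit, monitor = NULL) {
  stopifnot(inherits(fit, "dirt_fit"))
  all_groups <- c("beta", "gamma", "lam_delta", "lam_e", "lam_tau",
                  "rho", "lam_theta", "lam_eps")
  if (is.null(monitor)) monitor <- fit$config$monitor
  if (is.null(monitor)) monitor <- all_groups
  if (fit$dir_mode)
    monitor <- setdiff(monitor, c("gamma", "lam_tau", "rho", "lam_eps"))
  cols <- list()
  for (g in monitor) {
    dr <- fit$draws[[g]]
    if (is.null(dr)) stop("unknown monitor group: ", g)
    if (is.matrix(dr)) {
      colnames(dr) <- sprintf("%s[%d]", g, seq_len(ncol(dr)))
      cols[[g]] <- dr
    } else {
      cols[[g]] <- matrix(dr, ncol = 1, dimnames = list(NULL, g))
    }
  }
  do.call(cbind, cols)
}

## run one or more Gibbs blocks on an explicit state (testing hook)
gibbs_blocks <- function(dataset, state, priors, linkage, blocks,
                         grid_n = 301, grid_width = 8) {
  fl <- flatten_data(dataset)
  block_ids <- c(z = 1L, psi = 2L, b = 3L, delta = 4L, e = 5L, theta = 6L,
                 beta = 7L, time = 8L, precisions = 9L)
  ids <- block_ids[blocks]
  if (anyNA(ids)) stop("unknown block name")
  cpp_sweep(flat_for_cpp(fl), state, unclass(priors),
            linkage_code(linkage), as.integer(ids), grid_n, grid_width)
}
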