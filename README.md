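# dirt — dynamic item response models jointly fit with response times

`dirt` is an R package for inferring a learner's latent ability
trajectory from computerized-testing data in which two streams are
recorded at irregular, person-specific time points: dichotomous item
responses and the time taken to complete each test. Ignoring the times
throws information away; modelling them jointly with the responses both
tightens and de-biases the ability estimates. The intended users are
psychometricians and education researchers working with
computerized-(adaptive)-testing logs — randomized items, several tests
per day, local dependence within a day, and gaps of days to weeks
between sessions.

## The model

For person *i*, date *t*, test *s*, item *l*:

* **Item responses** (Rasch-type with local dependence):
  `P(Y = 1) = F(θ_it − b_itsl + δ_it + e_its)`, `F` the logistic cdf,
  with randomized difficulties `b ~ N(d_its, σ_b²)` around the test's
  known target `d`, daily effects `δ_it ~ N(0, 1/λ_δi)`, and test
  effects `e` summing to zero within a day.
* **Response times** (lognormal, test level):
  `log T_its = γ_i − τ_it + ρ·f(θ_it − d_its) + ε`, with person mean
  log-time `γ_i`, zero-mean daily speed deviation `τ_it`, and a linkage
  `f` that is either monotone (`f(x) = x`) or inverted-U (`f(x) = x²`,
  peak time at matched difficulty when `ρ < 0`).
* **Ability dynamics** (nonlinear growth Markov process):
  `θ_it = θ_i,t−1 + β_i·h̃·(1 − θ_i,t−1/θ_M) + N(0, h̃/λ_θ)`, where `h̃`
  is the lapse in days capped at `h_max` — long absences inflate the
  innovation variance.

Fitting is by a block Gibbs sampler: the logistic link is augmented as a
Kolmogorov–Smirnov scale mixture of normals so every block is conjugate;
ability paths are block-drawn by forward filtering / backward sampling
under the monotone linkage and date-by-date from the exact (grid)
conditional under the inverted-U linkage. Model comparison between the
two linkages uses Lindley's test on `ρ` and a partial DIC computed on the
response-time component with the speed deviations integrated out.

## A worked example

```r
library(dirt)

design <- default_design(persons = 10, dates = 15, tests = 2, items = 5)
sim <- simulate_dataset(design, sim_truth(10), "inverted_u", seed = 42)
fit <- run_chain(sim$data, dirt_priors(),
                 dirt_mcmc(n_iter = 2000, burn_in = 1000, seed = 7))
fit
#> <dirt_fit> inverted_u, 1000 retained draws, 10 persons
#>   posterior median rho = -0.3441
quantile(fit$draws$rho, c(.025, .975))
#>       2.5%      97.5%
#> -0.3718131 -0.3186491
```

The generating slope was −0.35: the posterior median lands at −0.344
with a 95% interval (−0.372, −0.319). Ability recovery on the same run
(`ability_summary(fit)` against the retained truth) gives a
root-mean-squared error of 0.12 logits with 96% of the true abilities
inside their pointwise 95% bands.

Removing the time table re-fits the item-responses-only reduction (the
DIR comparator) on identical data:

```r
fit_dir <- run_chain(make_dir_only_view(sim$data), dirt_priors(),
                     dirt_mcmc(n_iter = 2000, burn_in = 1000, seed = 7))
```

On replicated simulations from the packaged defaults the
responses-only fit has a mean-squared ability error several times that
of the joint fit (ratios around 4–11 at this reduced scale), with
uniformly wider credible bands — the quantitative case for modelling
the times.

Linkage comparison on a fitted model:

```r
lindley_test(fit$draws$rho, alpha = 0.05)   # reject rho = 0?
partial_dic(fit, sim$data)                  # smaller DIC = better linkage
```

A thin command line wraps the same functions
(`inst/cli/dirt simulate|fit|compare-linkage|coverage|report`); every
artifact-producing command writes a JSON run manifest.

## Acceptance script

`scripts/acceptance.R` recomputes the convergence acceptance quantity
from scratch against the installed package: it simulates a reduced
simulation-study dataset (10 persons × 25 dates × 4 tests × 10 items),
runs the inverted-U Gibbs sampler for 40,000 sweeps with burn-in at half
the chain, computes the Geweke z-statistic (10%/50% windows, AR spectral
variance) for every monitored scalar parameter, and writes the maximum
absolute value as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Package layout

* `R/model.R` — observation/system equations, complete-data
  log-likelihood, raw-score ability.
* `R/simulate.R` — the synthetic-data generator (all latent truth
  retained).
* `R/augment.R`, `src/dirt.cpp` — K-S scale-mixture augmentation,
  truncated normals, FFBS, single-site grid sampler, and the full Gibbs
  sweep (Rcpp).
* `R/gibbs.R` — configuration and the chain driver.
* `R/evaluate.R` — Lindley's test, partial DIC, posterior predictive
  check, Geweke diagnostic, coverage and DIR-vs-DIR-RT experiments.
* `R/io.R`, `R/cli.R` — CSV/JSON formats, manifests, command line.
* `vignettes/dirt-methods.Rmd` — the methods vignette: model,
  assumptions, priors, sampler validation, the stated synthetic world
  and its limits.
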