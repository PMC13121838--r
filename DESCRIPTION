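Package: dirt
Title: Dynamic Item Response Models Jointly Fit with Response Times
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Bayesian state-space modelling of longitudinal dichotomous item
    responses observed jointly with test-level response times at irregular,
    person-specific time points (the DIR-RT model family). Latent ability
    follows a nonlinear-growth Markov process with lapse-scaled innovation
    variance; item responses follow a Rasch-type logistic observation
    equation with randomized item difficulties and daily/test random
    effects; log response times follow a lognormal equation whose mean
    depends on person speed and on the ability-difficulty distance through
    a monotone or inverted-U linkage. Includes a block Gibbs sampler
    (Kolmogorov-Smirnov scale-mixture augmentation of the logistic link,
    forward-filtering backward-sampling ability draws under the monotone
    linkage, single-site grid draws under the inverted-U linkage), a
    synthetic-data simulator, linkage-comparison statistics (Lindley's
    test on the linkage slope, a partial deviance information criterion on
    the response-time component), convergence and coverage diagnostics,
    and CSV/JSON input-output with a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
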