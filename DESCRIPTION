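Package: pavarb
Title: Bayesian Arbitration Between Pavlovian and Instrumental Control
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for reward Go/No-Go tasks with a
    controllability manipulation. Implements Beta-Bernoulli Pavlovian
    (stimulus-only) and instrumental (stimulus-action) reward learners, a
    Bayesian model-averaging arbitrator that weights the two controllers by
    the posterior log-odds that the environment is uncontrollable, and a
    fixed-weight comparison model. Provides maximum-likelihood fitting with
    multistart, random-effects Bayesian model selection (expected
    frequencies, exceedance probability, Bayes omnibus risk, protected
    exceedance probability), Go-bias analyses (weight quantiles, trial
    timecourse), a bias-variance decomposition of choice behavior, and an
    end-to-end reproducible pipeline on synthetic cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
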