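Package: metapsi
Title: Simulation and Preregistered Analysis Battery for Forced-Choice
    Guessing Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for metascientific replication studies of forced-choice
    precognition experiments in the Bem Experiment 1 paradigm. Provides a
    trial-level simulator of 36-trial guessing sessions with sham trials,
    random-event-generator (REG) counterfactual arms, participant
    heterogeneity and injectable systematic biases; directional Bayes-factor
    proportion tests under uniform, knowledge-based and replication beta
    priors; intercept-only random-intercept logistic regression fitted by
    Gauss-Hermite quadrature with probability-scale Wald intervals; the
    preregistered three-look sequential design with its four-test all-agree
    stopping rule; Monte-Carlo power and sample-size determination; and
    calibration diagnostics for class-A systematic error on counterfactual
    arms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
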