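Package: gainlossr
Title: Simulation and Analysis of the GainLoss Probabilistic Selection Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing a three-pair probabilistic
    selection ("GainLoss") task used to test whether dopaminergic drugs
    affect the expression of reinforcement learning. Provides the task
    engine (symbol contingencies, learning and feedback-free transfer
    schedules, outcome sampling, optimal-response coding), trial-level
    dual-learning-rate Q-learning and opponent actor (OpAL) models with
    exact choice log-likelihoods, per-subject maximum-likelihood fitting
    with BIC model comparison and recovery harnesses, behavioural choice
    metrics (accuracy, choose/avoid percentages, learner thresholds,
    weight-adjusted dose), the study's statistical battery (paired t-tests
    with Cohen's d, JZS Cauchy-prior Bayes factors and posterior effect
    summaries, repeated-measures ANOVA with Greenhouse-Geisser correction,
    exact binomial tests, dose-response regressions), and a synthetic
    within-subject crossover cohort generator so the full pipeline runs
    end-to-end without any external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
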