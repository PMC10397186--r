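Package: relforage
Title: Relational Search Templates in Visual Foraging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and hierarchical Bayesian analysis of human visual
    foraging with distractors of varying colour relationships to the target.
    Generates synthetic click-event logs with the structure of a multi-target
    foraging experiment (patches of 90 moving stimuli, four within-subject
    distractor conditions, marginal-value-theorem patch leaving), computes
    foraging statistics (rate of return, proportion of targets left behind,
    inter-target times, selection delays), screens participants and trials,
    fits hierarchical Normal and beta-binomial models in free and
    order-constrained variants via JAGS, compares the relational and
    feature-specific accounts of attention guidance with Pareto-smoothed
    importance-sampling leave-one-out cross-validation and stacking weights,
    and runs auxiliary analyses (highest-density intervals, posterior
    contrasts, JZS paired Bayes factors, repeated-measures correlation,
    patch-leaving tests against the environment's average rate of return).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    dplyr,
    tibble,
    tidyr,
    ggplot2,
    jsonlite,
    yaml,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
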