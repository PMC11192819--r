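Package: recalleval
Title: Memory Sampling and the Evaluation of Number Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and Bayesian analysis of a sequence-evaluation
    experiment in which participants view short sequences of numerical
    values, freely recall them, and bid for another draw from the sequence
    in an incentive-compatible Becker-DeGroot-Marschak auction. The package
    generates synthetic experiments with the task's statistical structure
    (serial-position-structured recall, counterbalanced task order, auction
    payoffs), computes trial-level predictors of willingness to pay for
    four candidate evaluation models (recalled-items mean, presented-items
    mean, both, and a temporal-difference value-updating rule), fits the
    models as Bayesian hierarchical regressions via JAGS, compares them by
    bridge-sampling marginal likelihoods and Bayes factors, classifies
    per-participant strategies with a latent mixture model, validates the
    comparison with a model-recovery confusion matrix, and provides the
    behavioural descriptives (exclusion filters, serial-position curves
    with within-subject error bars, bid accuracy).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    coda,
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rjags,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
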