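Package: locuspred
Title: Simulation and Analysis of Counting-Recursion Learning in the Locus
    Prediction Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how learners acquire a counting-recursion
    language (a variant of a^n b^n) in the Locus Prediction paradigm, where a
    prediction is collected at every symbol of a long box-highlighting
    sequence.  The package generates the experimental symbol sequences under
    the task's ordering constraints, simulates cohorts of synthetic learners
    embodying competing hypotheses (finite-state bearing-point grammars,
    incremental backoff n-gram predictors, progression-plus-noise,
    probabilistic mixtures of grammars, and dynamical post-error
    perturbation), scores trial- and sentence-level prediction accuracy,
    classifies per-sentence behavior into bearing-point grammar states,
    and runs the associated statistical analyses: spontaneous-generalization
    tests with exact binomial confidence intervals, grammar-stage progression
    statistics, variance-vector cosine interpolation analysis, and
    conditional post-error accuracy contrasts with cluster-bootstrap
    logistic fits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    jsonlite,
    yaml,
    withr,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
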