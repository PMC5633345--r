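Package: vollearn
Title: Valence-Specific Volatility Learning: Task Generation, Model Fitting
    and Pupillometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how learners weight positive and negative
    outcomes according to how informative (volatile) each outcome is.
    Generates dual-valence probabilistic learning-task schedules in which
    the volatility of win and loss outcomes is manipulated independently,
    simulates choice behaviour under five reinforcement-learning model
    variants (including a fully Bayesian volatility-tracking learner),
    estimates model parameters by full grid posterior with marginal
    expectations, compares models by BIC, synthesises and preprocesses
    outcome-locked pupillometry traces, and runs the group-level
    repeated-measures analyses linking learning rates and pupil responses
    to outcome volatility.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
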