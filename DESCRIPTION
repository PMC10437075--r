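Package: seqstrat
Title: Simulation and Strategy Analysis of Markov Sequence Prediction Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for simulating and analysing prediction-task experiments in
    which observers learn first-order Markov structure from symbol streams.
    Builds four-state transition models with two-target contingencies,
    generates structured and random trial sequences with fixed or jittered
    inter-stimulus intervals, simulates synthetic participants whose decision
    policies span random guessing, probability matching and maximization
    (including a pseudo-count learning agent modulated by feedback regime),
    and computes the behavioural measures used to characterise such learning:
    the minimum-overlap Performance Index with its random-guess baseline and
    learner classification, Kullback-Leibler strategy choice per block, and
    the integral-curve-difference strategy index. Includes a two-down one-up
    adaptive staircase simulator for cognitive covariates and cohort-level
    correlation and incremental variance analyses for parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
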