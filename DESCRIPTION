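Package: avoidrl
Title: Reinforcement-Learning Models of Avoidance in Probabilistic Reward
    and Punishment Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a three-option (categorize "A", categorize "B", or
    skip) probabilistic classification task with reward and punishment
    outcomes, fits a six-parameter Q-learning model -- asymmetric learning
    rates, softmax temperature, and subjective values of the ambiguous
    no-feedback outcome and of post-avoidance feedback -- and five
    constrained variants to per-subject trial logs by exhaustive
    grid-search maximum likelihood. Models are compared with the Bayesian
    Information Criterion and a random-effects Bayesian model selection
    procedure (variational Dirichlet updates and Monte Carlo exceedance
    probabilities). Includes behavioral phenotyping (avoider and
    frequent-avoider classification, optimal and adaptive responding,
    rank correlations between fitted parameters and avoidance), a seeded
    synthetic-cohort generator for parameter- and model-recovery studies,
    and a command-line front end chaining simulate, fit, compare and
    report stages.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
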