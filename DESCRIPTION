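Package: drtlearn
Title: Reinforcement Learning and Matching-Law Analysis for the Dynamic
    Reward Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for the dynamic reward task,
    a two-deck probabilistic choice task whose deck reward probabilities
    swap across unsignaled blocks while the total gain probability stays
    fixed at 0.6.  Provides the task schedules and reward generator, a
    Q-learning model with a softmax choice rule (learning rate and choice
    perseveration), generalized matching-law regression with steady-state
    filtering and group slope comparisons, hierarchical Bayesian
    estimation of subject- and group-level parameters by adaptive
    Metropolis-within-Gibbs MCMC with posterior group-difference
    probabilities and Savage-Dickey Bayes factors, a synthetic cohort
    generator emulating a three-group psychosis/control study design, and
    a grid simulation quantifying how learning rate and perseveration
    shape total task score.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
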