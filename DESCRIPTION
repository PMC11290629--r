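Package: bccsim
Title: Joint Simulation of Choices and Reaction Times by Bayesian
    Contextual Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates joint choice and reaction-time data from a Bayesian
    contextual control agent. Planning is an independence Metropolis-Hastings
    sampler over context-specific policies whose proposals come from a learned
    Dirichlet habit prior and whose acceptance ratio uses a goal-directed
    reward likelihood; sampling stops once the entropy of an online Dirichlet
    posterior estimate falls below a certainty threshold, and the number of
    samples maps linearly to milliseconds. Includes three closed-loop task
    environments (a 4x5 grid world with a mid-experiment goal switch, an
    Eriksen flanker task, and a cued task-switching paradigm), ablation
    toggles, and analysis helpers for conditional accuracy functions, Gratton
    sequential effects, learning curves, switch costs and reaction-time
    distribution shape.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    jsonlite,
    nortest,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
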