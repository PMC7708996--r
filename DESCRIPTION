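Package: moodnet
Title: Agent-Based Simulation of Mood Disorders in Social Interaction Games
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates societies of rational, manic, depressed, and bipolar
    agents playing an iterated Continuous Prisoner's Dilemma on a social
    network. Agents appraise rewards against expectations to generate emotion,
    integrate emotion into mood, encode interaction memories with
    emotion-weighted strength, forget along an exponential decay curve, and
    retrieve memories with mood-congruent (triangular-kernel) selectivity.
    Mania and depression are modelled through reward sensitivity, which also
    scales an agent's drive to participate and the size of its personal
    network; bipolar mood follows a rhythmic sinusoid with resampled angular
    rate. Includes a fast compiled round engine, seeded parameter sweeps over
    forgetting rate, emotional encoding bias, mood dependence, population
    composition, and reward sensitivity, plus tidy summaries and plots of
    comparative payoffs by agent type.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
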