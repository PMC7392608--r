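Package: habitsim
Title: Simulating Dopaminergic Prediction Errors in Action Planning and Habit Formation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A trial-based simulator of a basal-ganglia model in which
    dopaminergic prediction errors drive both within-trial action planning
    (gradient dynamics on a maximum-a-posteriori objective combining a
    goal-directed reward likelihood and a habit prior) and between-trial
    learning (three-factor plasticity rules and precision updates). Includes
    a continuous-time temporal-difference valuation system with eligibility
    traces, a single-action intensity actor, a two-action choice actor with
    competitive dynamics, and scripted experimental protocols (acquisition,
    dopamine-depletion probes, outcome devaluation, Pavlovian-instrumental
    transfer, and reversal learning) producing tidy per-trial records and
    binned summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
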