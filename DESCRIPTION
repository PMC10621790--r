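Package: mipdtrial
Title: Simulation of Clinical Trials for Model-Informed Precision Dosing of Warfarin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A framework for simulating clinical model-informed precision dosing
    (MIPD) trials, using warfarin anticoagulation as the use case. A clinical
    trial model with five independent components (a mechanistic warfarin PKPD
    model, a covariate-aware mixed-effects population model, inter-occasion
    variability of the vitamin K input, execution deviations from nominal
    schedules, and lognormal measurement noise) generates virtual cohorts and
    noisy INR monitoring data. Three dosing agents individualise daily warfarin
    doses against a target INR: feed-forward neural-network regression of the
    maintenance dose, a Double-DQN reinforcement-learning policy, and Bayesian
    MAP individualisation of a hierarchical PKPD model with CMA-ES regimen
    optimisation. Pre-MIPD trial protocols (phases I-III), the MIPD trial loop,
    and outcome metrics (maintenance INR, peak INR, time in therapeutic range,
    success rate) are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
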