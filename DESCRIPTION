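Package: avoidsim
Title: Simulation and Analysis of Free-Movement Avoidance-Conditioning Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless, desk-scale toolkit for room-scale human avoidance
    conditioning paradigms. Provides a declarative task engine (virtual room,
    distance-decaying aversive sound, conditioned stimuli on a pedestal,
    phase/trial schedules with partial reinforcement and counterbalancing),
    simulated participants driven by delta-rule conditioned-stimulus learning
    and a distance-regulating movement policy, session logging in a
    one-row-per-trial plus one-movement-file-per-tracker-per-trial layout,
    extraction of seven trial-level kinematic summary statistics from head
    trajectories, and the matching statistical layer: paired Cohen's d and
    Hedges' g with noncentral-t confidence intervals, linear mixed-effects
    contrasts within and across experimental phases, and sensitivity power
    analysis for paired t tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lme4,
    lmerTest,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
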