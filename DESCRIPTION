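Package: horizonnoise
Title: Random and Deterministic Decision Noise in the Repeated-Games Horizon Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of the repeated-games Horizon Task, an
    explore-exploit bandit paradigm in which every game of forced-choice
    trials is presented twice so that choice consistency across repeats can
    separate stimulus-driven ("deterministic") decision noise from per-play
    ("random") decision noise. Provides a synthetic task and session
    generator, a generative two-noise logistic choice agent that freezes
    deterministic noise within repeated game pairs, model-free exploration
    and consistency statistics with analytic pure-random and
    pure-deterministic bounds, a hierarchical Bayesian model (fit with JAGS)
    that estimates information bonus, spatial bias and the two noise spreads
    per subject and horizon, and validation machinery: parameter recovery,
    shuffled controls, reduced-model detection and posterior predictive
    checks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    rjags,
    coda,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
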