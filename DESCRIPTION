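Package: voigame
Title: Simulation and Analysis of Veil-of-Ignorance Redistribution Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for simulating and analysing repeated-round redistribution
    games played behind and without a veil of ignorance. Provides the game
    payoff engine (three redistribution rules with a deadweight transfer
    cost), a synthetic cohort generator (softmax-utility agents with maximin
    or expected-value risk handling, feeling-thermometer affect ratings, and
    trial-level region-of-interest outcomes), the accordance/non-accordance
    affective classification with its exclusion accounting, a
    baseline-invariant decomposition of condition-by-decision interaction
    effects (tau, psi, pi), and behavioural statistics including a
    participant-level cluster bootstrap.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
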