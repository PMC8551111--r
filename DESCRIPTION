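Package: chasepred
Title: Chase-Escape Trajectory Analysis and Opponent-Motion Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing one-on-one chase-escape (pursuit-evasion)
    trajectories recorded on a bounded pitch, and for learning predictors of
    opponent motion. Includes an agent-based simulator of speed-capped
    attacker/defender disks, detection of horizontal direction changes by
    velocity zero crossing, response-time and short-latency analysis,
    heading-change entropy, inter-switch interval (memorylessness) analysis,
    linear and curvilinear extrapolation baselines, and a family of neural
    sequence predictors (linear, nonlinear, recurrent, LSTM and deep
    variants) with a bivariate-Gaussian output head trained by negative
    log-likelihood, evaluated one step ahead and by closed-loop multi-step
    rollout (ADE/FDE) under leave-one-participant-out cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
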