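Package: grfest
Title: Ground Reaction Force and Moment Estimation from EMG and IMU Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the six-channel ground reaction wrench (Fx, Fy, Fz,
    Mx, My, Mz) during posture control and stepping motions from surface
    electromyography (EMG) and inertial measurement unit (IMU) recordings.
    Implements the full pipeline: a synthetic biomechanical session
    generator built on an inverted-pendulum sway model, Butterworth
    filtering and linear-envelope extraction with multi-rate resampling to
    a common 74.074 Hz timebase, a long short-term memory (LSTM) regressor
    written from its gate equations with Adam training, percent-RMSE
    evaluation with per-group mean and standard error aggregation, and
    support-vector-machine decoding of stepping direction from the
    estimated force in the early phase of a step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
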