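Package: painlimits
Title: Pain-Onset Biomechanical Limits for Physical Human-Robot Interaction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Turns repeated pain-threshold load tests (quasi-static pinching
    ramps from an algometer and stepped pendulum impact staircases) into
    biomechanical safety limits for collaborative robots. Provides raw-signal
    conditioning (channel-frequency-class zero-phase Butterworth filtering,
    offset elimination, inertia compensation), pressure-film frame processing
    (per-view Gaussian blur, blind-spot spline interpolation, force
    calibration), interval censoring with midpoint imputation, maximum
    likelihood fitting of a log-logistic accelerated failure time model with a
    gender covariate, quantile limit tables with delta-method confidence
    intervals for arbitrary percentiles and gender mixes, and cross-study
    comparison statistics. A synthetic-data module generates subject
    populations and raw trial signals with known ground-truth thresholds so the
    whole pipeline is testable without human-subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    knitr,
    optparse,
    rmarkdown,
    survival,
    testthat (>= 3.0.0),
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
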