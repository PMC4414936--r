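Package: emgangle
Title: Continuous Elbow-Joint Angle Estimation from Single-Channel Surface EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Estimates the continuous elbow-joint angle during voluntary
    flexion and extension in the sagittal plane from a single channel of
    surface electromyography (EMG) recorded over the biceps brachii. Raw EMG
    is high-pass filtered, rectified, passed through a second-order recursive
    activation-dynamics filter with electromechanical delay, low-pass
    smoothed, normalized to maximum voluntary contraction and mapped through
    an exponential activation nonlinearity. A Hill-type musculotendon model
    motivates a quadratic map between muscle activation and the squared
    cosine of the elbow angle, fitted per subject from one calibration trial.
    A four-state switching model (relaxation, flexion, holding, extension)
    with a proportional-gain continuity correction converts the activation
    trace into a continuous angle trace. A synthetic surface-EMG generator
    (amplitude-modulated band-limited Gaussian noise driven by the forward
    model, including the flexion-to-holding activation overshoot) makes the
    whole pipeline testable without human recordings.
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
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
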