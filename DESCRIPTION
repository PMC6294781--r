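Package: mosgait
Title: Margin-of-Stability Gait Analysis for Treadmill Belt-Acceleration
    Perturbation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying dynamic gait stability from a reduced
    five-marker treadmill model (C7, both trochanters, both halluces).
    Implements anteroposterior margin-of-stability (MoS) computation from the
    extrapolated centre of mass, zero-phase Butterworth preprocessing, hybrid
    marker/force-plate gait-event detection with force-based correction,
    stability-normalised walking-speed determination by quadratic inversion of
    the MoS-speed relationship, a treadmill belt-acceleration perturbation
    protocol engine, and recovery-step metrics with repeated-measures
    statistics for quantifying adaptation, retention, savings and interlimb
    transfer. Includes a synthetic motion-capture generator with controlled
    ground truth so the full pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
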