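Package: saccadeflow
Title: Saccade Kinematics and Pupillometry Analysis for Oculomotor Pharmacology Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for oculomotor assessments in
    placebo-controlled crossover studies: resting pupil-diameter
    preprocessing (blink padding, interpolation, Hann smoothing,
    windowed quality control and z-scored means), prosaccade and
    antisaccade trial parsing with validity gates and participant-level
    outlier filters, peak-velocity residuals and time-normalized
    velocity profiles, square-root main-sequence modelling with
    bootstrap confidence intervals and normative deviation scores, and
    default Jeffreys-Zellner-Siow Bayes factors for one- and two-sample
    t designs. A synthetic cohort generator with known ground-truth
    kinematic parameters drives end-to-end testing without external
    eye-tracking data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
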