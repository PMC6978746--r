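Package: armsense
Title: Hand-Gesture Recognition from a Piezoresistive Forearm Armband
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for a three-sensor
    force-sensitive-resistor (FSR) armband that recognizes eight hand
    gestures from forearm-muscle contraction forces. Provides a synthetic
    generator for multichannel 1 kHz force recordings with the protocol
    structure of a calibration session (trapezoidal contraction bursts,
    fastening preload, sensor noise, inter-subject variability), a linear
    current-mirror transduction model with ADC quantization, rest-offset
    subtraction and peak-to-peak threshold segmentation, per-segment
    mean/SD feature extraction, from-scratch linear discriminant, quadratic
    discriminant, one-vs-one soft-margin linear SVM and k-nearest-neighbour
    classifiers with stratified k-fold and leave-one-out cross-validation,
    sensor-subset ablation, a two-session reproducibility evaluation, and a
    fixed-rate sliding-window streaming decoder emitting one-byte gesture
    codes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    e1071,
    class,
    optparse
Config/testthat/edition: 3
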