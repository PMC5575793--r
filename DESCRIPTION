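Package: touchtrace
Title: Quantification of Stimulus-Evoked Calcium Imaging in C. elegans
    Mechanosensory Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for quantifying stimulus-evoked calcium
    transients recorded from fluorescently labeled C. elegans
    mechanosensory neurons in two-channel (GCaMP/RFP) time-lapse stacks:
    frame-by-frame neuron tracking, top-k-brightest-pixel ROI intensity
    extraction with background subtraction, ratiometric motion-artifact
    correction, baseline normalization to dR/R0, per-trial response
    metrics (peak, delay time, half-life, responder classification),
    dose-response and habituation summaries, and nonparametric
    drug-screen statistics with per-day control normalization. A
    synthetic two-channel scene generator with known ground truth
    (neuron path and true calcium trace) replaces the microscope so
    every stage of the chain is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
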