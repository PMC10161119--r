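Package: spotrobust
Title: Spot Delivery Error Modelling and Robustness Evaluation for
    Pencil-Beam Scanning Proton Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how pencil-beam scanning spot delivery errors
    affect intensity-modulated proton therapy (IMPT) plan robustness.
    Generates pulse-level machine log files and QA spot grids with a known
    error structure, aggregates pulses into delivered spots, quantifies
    agreement between measured and log-recorded spot positions, trains a
    small feedforward network that maps planning parameters to delivered
    spot position and monitor units, writes pseudo log files from the
    predictions, recomputes dose with a simplified analytic pencil-beam
    engine including aperture collimation, and evaluates plan robustness
    with multi-scenario banded dose-volume histograms, worst-case DVH
    indices and a 95/95 coverage verdict.
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
    rlang,
    stats,
    tibble,
    tools,
    utils,
    grDevices
Suggests:
    mgcv,
    nnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
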