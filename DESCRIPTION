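Package: cardiosens
Title: Dual-Readout Impedance and Cantilever Analysis for Cardiomyocyte
    Drug Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis toolkit for dual-readout cardiomyocyte biosensors
    that combine electric cell-substrate impedance sensing (ECIS) on
    interdigitated electrodes with cantilever-based contraction-force
    transduction.  Provides an equivalent-circuit forward model (series
    resistance, constant-phase element, cell-electrode RC branch) with
    complex nonlinear least-squares fitting, cell-index and normalized
    resistance time-course analysis, beat detection and per-beat
    contraction metrics from displacement traces, dose-dependent drug
    suppression/recovery profiling with optional Hill/IC50
    summarization, and a seeded synthetic-data generator that emulates
    the physical device for testing and calibration.
License: MIT
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'device-model.R'
    'eis-model.R'
    'eis-fit.R'
    'eis-normalize.R'
    'beats.R'
    'drug-response.R'
    'keyframes.R'
    'synthetic.R'
    'io.R'
    'run.R'
    'utils.R'
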