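Package: mitopore
Title: Amplification-Free Mitochondrial DNA Copy-Number Analysis for
    Solid-State Nanopore Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying mitochondrial DNA (mtDNA) copy number from
    solid-state nanopore ion-current recordings without amplification.
    Provides a statistically calibrated simulator of translocation traces and
    synchronous photon-count series, robust open-pore baseline estimation and
    blockade event detection, extraction of per-event features (fractional
    blockage, dwell time, in-event current RMS), a Gaussian-kernel support
    vector machine event classifier with stratified cross-validation, digital
    single-molecule count ratios with binomial confidence intervals, spike-in
    calibration fitting to recover endogenous copy numbers, and
    electro-optical burst/translocation synchrony analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
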