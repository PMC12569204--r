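Package: epiassay
Title: Quantitative Assay Pipelines for Epigenome-Editing Studies
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tested pipelines for two quantitative readouts commonly used to
    validate locus-specific epigenome editing. The first estimates the
    methylation fraction of an amplicon from methylation-sensitive
    restriction-digestion qPCR (HpaII/MspI-style assays) via relative
    amplification, standard-curve calibration with inverse prediction,
    digestion quality control, and comparative delta-delta-Ct expression
    quantification. The second detects spontaneous calcium transients in
    ROI fluorescence time series using delta-F-over-F0 normalization
    against a low-percentile baseline, a difference-pattern candidate
    search, a median-absolute-deviation dynamic threshold, interval-based
    event de-duplication, and per-cell activity rates. A synthetic-data
    module simulates both assay types with known ground truth so the full
    pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
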