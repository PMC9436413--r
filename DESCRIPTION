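Package: dopaflow
Title: Dopamine Photometry, Voltammetry and Operant Self-Administration Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for mesolimbic dopamine experiments: dual-channel
    fiber-photometry delta-F/F construction with control-channel regression and
    rolling z-score transient detection; fast-scan cyclic voltammetry electrode
    calibration, evoked-release peak extraction and exponential reuptake (tau)
    fitting; and operant self-administration schedule analytics (fixed-ratio,
    multiple-dose and progressive-ratio sessions, breakpoint, acquisition and
    stability criteria, dose-response curves). Ships seedable synthetic-data
    generators for all three data streams so every stage is testable against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
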