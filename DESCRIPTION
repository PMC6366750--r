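Package: oscpls
Title: Task and Behavioural Partial Least Squares for Source-Space
    Oscillatory Power
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mean-centered task partial least squares (PLS) and behavioural
    PLS for band-limited oscillatory power extracted from source-space
    virtual channels, with permutation tests on singular values and
    bootstrap estimation of salience reliability.  Includes a short-time
    Fourier spectral stage for band power in task windows, behavioural
    summaries (accuracy, correct-trial response times, outlier and
    response-locked trial selection rules), and a synthetic-data generator
    that emulates a two-group, multi-phase visuospatial memory design with
    planted group-by-phase power effects and brain-behaviour couplings, so
    every stage of the pipeline can be verified against known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
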