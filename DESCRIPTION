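Package: mxsqueeze
Title: Lossy and Lossless Compression Operators for Rotation-Series
    Diffraction Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Compression toolkit for fine-phi-sliced macromolecular
    crystallography frame stacks. Implements the CBF byte-offset lossless
    codec used as the baseline for extra compression ratios, an integer
    Haar H-transform codec with a quantization scale (the Hcompress
    family), pixel binning and frame summing with correct detector and
    scan metadata propagation, composable pipelines such as
    BIN2_SUM2_HCOMP16, and impact metrics: compression reports with extra
    compression ratios, Bragg reflection profile extraction, a four-way
    peak-survival classification, stack-level over-compression summaries,
    and a variance-normalized real-space R for density grids. Ships a
    synthetic rotation-series generator (Poisson background, Gaussian
    peaks with phi-partiality, detector gap stripes) with per-peak ground
    truth for benchmarking.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
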