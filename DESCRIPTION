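Package: periscan
Title: Periodic Patterns in Genome Layout and Multi-View Prediction of
    Transcription-Factor Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Systematic detection of long-range periodic arrangement of
    co-regulated genes along a chromosome, and prediction of
    transcription-factor targets from the combination of binding-site
    sequence scores and gene-position scores.  The layout analysis scans all
    candidate periods with a circular-concentration score and exact
    Monte-Carlo calibrated p-values, clusters features that are in-phase on
    circular phase coordinates with a deterministic DBSCAN, and maps genomic
    sub-regions carrying a local periodic pattern with a variable-size
    sliding window.  The prediction half trains a multi-view boosting
    classifier on position weight matrix log-odds and positional scores, and
    quantifies the interplay of the two views by regularised canonical
    correlation analysis.  Synthetic-data generators with planted ground
    truth support benchmarking without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    ggplot2,
    Biostrings,
    BiocGenerics,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mixOmics,
    optparse
Config/testthat/edition: 3
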