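Package: TruDropDesign
Title: Dual-Indexed inDrop Library Design, Index-Hopping Simulation and
    Sequencing Quality Control
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Toolkit for the dual-indexed TruSeq-inDrop (TruDrop) single-cell
    RNA-seq library design. Encodes the TruSeq, inDrop V2 and TruDrop library
    structures as sequence templates, derives sequencing primers and screens
    cross-structure mispriming hazards; validates sample-index sets (edit
    distance, unique-dual indexing) and implements the unanticipated index
    combination filter for index-hopped reads; models cross-sample cell
    barcode collision under index hopping both analytically and by Monte
    Carlo; simulates pooled dual-indexed sequencing runs with configurable
    index hopping and demultiplexes them; parses inDrop barcode reads
    (variable-length barcode 1, W1 spacer, barcode 2, UMI, poly-T); and
    computes sequencing quality statistics (per-cycle Q30, region-weighted
    quality, base-call error probabilities, exact Mann-Whitney tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: SingleCell, Transcriptomics, Sequencing, QualityControl,
    Preprocessing
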