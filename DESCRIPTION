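Package: adtcount
Title: Antibody-Derived Tag Counting for ASAP-seq and CITE-seq
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Converts paired FASTQ files from antibody-tag sequencing
    experiments (ASAP-seq, CITE-seq) into a deduplicated, CellRanger-style
    feature-by-barcode count matrix. One read of each pair carries the cell
    barcode and UMI, the other the antibody-oligo tag. Cell barcodes are
    matched against a whitelist by Hamming distance and tags against an
    oligo reference panel by a normalized edit-distance ratio; reads
    matching multiple references are dropped as ambiguous, duplicated UMIs
    are collapsed (exact or 1-mismatch fuzzy), and the surviving molecules
    are written as a MatrixMarket sparse triplet with barcode and feature
    annotation files. A seeded simulator generates paired FASTQ data with
    known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    Matrix,
    Rcpp,
    igraph,
    parallel,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
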