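Package: mirest
Title: Homology-Based Mining of MicroRNAs and Their Targets from EST
    Collections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies candidate plant microRNAs in expressed sequence
    tag (EST) collections by mismatch-bounded homology search against a
    reference set of mature miRNAs, excludes likely protein-coding
    sequences, validates candidate precursors by hairpin folding with
    MFE/AMFE/MFEI metrics, and predicts miRNA target sites with an
    expectation-scored complementarity scan that classifies cleavage
    versus translational repression. Includes a synthetic-data generator
    that plants hairpins and target sites with a ground-truth manifest
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
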