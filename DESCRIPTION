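Package: colbwt
Title: Co-Linear Burrows-Wheeler Indexing with Chain Statistics for Read
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a co-linear Burrows-Wheeler transform (col-BWT) index over a
    collection of DNA sequences. Multi-maximal unique matches (multi-MUMs) are
    computed from the suffix array, converted into non-overlapping BWT tunnels by
    contiguous forward stepping, and marked as identifier-carrying sub-runs of a
    run-length encoded BWT. Queries return pseudo-matching lengths together with
    chain statistics (per-position tunnel identifiers) in a single right-to-left
    pass, and a peak-based classifier uses co-linear peak pairs to decide whether
    long, error-bearing reads originate from the indexed pangenome. A synthetic
    pangenome and read simulator makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    optparse,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
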