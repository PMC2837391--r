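Package: mpssr
Title: MPSS Tag-Count Transcriptome Profiling with Exact-Test
    Differential Expression and Signature-Based Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of massively parallel signature sequencing (MPSS)
    tag-count libraries: reliability filtering and tags-per-million (TPM)
    normalization of fixed-length DpnII-anchored signatures, per-signature
    pairwise differential expression by Fisher's exact test with
    Benjamini-Hochberg false-discovery-rate control, exhaustive
    DpnII-anchored matching of signatures to unigene/EST sequences with
    mismatch validation and annotation transfer, gene-family inference by
    single-linkage clustering of signature Hamming distances with
    data-driven mismatch-threshold calibration, and within-family
    expression co-regulation scoring. Includes a ground-truthed synthetic
    MPSS library generator (multinomial sampling over planted gene,
    family, fold-change and artifact structure) so every stage of the
    pipeline is testable without access to raw sequencing libraries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    Rcpp,
    rlang,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
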