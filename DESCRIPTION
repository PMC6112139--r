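Package: srnakit
Title: Small RNA-Seq Quantification, IsomiR Reporting, A-to-I Editing and
    Novel miRNA Discovery
Version: 0.1.0
Authors@R:
    person("srnakit", "developers", email = "srnakit@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for small RNA sequencing analysis:
    adapter trimming and collapsing of reads into unique sequences, cascade
    annotation against user-supplied RNA libraries with isomiR-tolerant
    miRNA assignment and a canonical-ratio filter, miRTop-style GFF3 isomiR
    reporting with CIGAR strings, A-to-I editing detection with four
    exclusion criteria, and a novel miRNA discovery engine that clusters
    unannotated reads on a genome, derives a stable read range, computes
    compositional and hairpin-structural features, and classifies candidate
    precursors with an mRMR-selected RBF support vector machine. A
    synthetic-data generator reproduces the statistical structure the
    method assumes (stable 5' ends, ragged 3' ends, non-templated A/U
    tails, planted hairpins and editing sites) for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    Rcpp,
    jsonlite,
    methods,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
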