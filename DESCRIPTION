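Package: embryochron
Title: Temporal Inference for Single-Nucleus Atlases of Embryogenesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Infers absolute developmental age of single nuclei profiled from
    overlapping timed embryo collections, and builds the downstream analyses
    that such ages enable: fine-time pseudobulk dynamics around zygotic genome
    activation, cell-state lineage graphs linked across inferred time windows,
    RNA-to-ATAC cluster integration by non-negative least squares, motif-level
    transcription-factor activity modeling across germ layers and time, and
    temporal gene-module discovery by dynamic time warping. Ships a synthetic
    multi-window atlas generator with planted ground truth (kinetic classes,
    lineage branching, pioneer accessibility leads, contamination, sex-linked
    read fractions) so that every stage can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    stats,
    utils,
    glmnet,
    igraph,
    mclust,
    pracma,
    withr,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
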