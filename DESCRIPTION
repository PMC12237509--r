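Package: scregulon
Title: Single-Cell Enhancer, Super-Enhancer and Gene-Marker Calling from scATAC-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls tissue/cell-type-specific regulatory elements from
    single-cell ATAC-seq data kept in count (non-binarized) form. Consensus
    ("typical") enhancers are scored by weighting every cell with its
    Tanimoto similarity to the rest of the population and filtering the
    weighted peak signal through four quality criteria (cell support,
    promoter/exon exclusion, a genome-shuffle null, and promoter
    co-accessibility). Enhancer-promoter links come from a
    distance-penalized graphical-lasso partial-correlation model fitted on
    metacell-aggregated, TF-IDF/LSI-embedded counts. Super-enhancers are
    called per cell type from fragment files by stitching candidate
    enhancers, ranking integrated signal, and cutting the rank curve at its
    slope-one tangent point; gene markers come from promoter-plus-gene-body
    activity scores tested one-vs-rest. Interval-overlap validation against
    reference catalogues uses union-based hypergeometric tests and
    base-pair Jaccard similarity. A seeded simulator with planted
    enhancers, super-enhancer clusters, co-accessible pairs and marker
    genes makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    readr,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    uwot,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
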