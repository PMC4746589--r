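Package: madsfam
Title: Genome-Wide MADS-Box Gene Family Mining, Phylogeny, Expression and
    Regulatory Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully testable re-implementation of the classic
    genome-wide transcription-factor family workflow used for the apple
    MADS-box family: profile-based family mining with two-stage domain
    confirmation and empirical e-values, positional nomenclature, collinearity
    chaining and tandem/proximal/segmental/dispersed duplication
    classification, neighbor-joining phylogenies with bootstrap bipartition
    support and clade-anchored DAM/FLC-like calling, FPKM expression
    profiling across phenological stages with delta-delta-Ct fold changes,
    IUPAC cis-element scanning of promoters, ChIP-peak-filtered TF target
    prediction, and protein-interaction network topology (power-law degree
    fit, hub detection) with hypergeometric GO enrichment. A synthetic-data
    module generates every input with machine-readable ground truth so each
    stage can be verified against planted signals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    igraph,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
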