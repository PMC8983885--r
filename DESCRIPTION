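Package: paralogr
Title: Comparative Genomics of Gene-Family Paralogy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for resolving paralogous subgroups within a gene family
    that arose through rounds of whole-genome duplication. Implements
    intron position and phase mapping onto protein multiple sequence
    alignments, genomic-neighborhood (synteny) extraction and comparison,
    neighbor-joining phylogenies from JTT maximum-likelihood distances
    with optional discrete-Gamma rate heterogeneity, column bootstrap
    with midpoint rooting, and homology classification from pairwise
    alignment coverage profiles. A ground-truthed simulator of a
    two-round duplication scenario (sequence divergence, intron gain and
    loss, lineage-specific gene loss, decaying gene neighborhoods)
    provides labeled inputs for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    jsonlite,
    Rcpp,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse
Config/testthat/edition: 3
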