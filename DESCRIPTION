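Package: phylopan
Title: Phylogenomic Species Delimitation and Pangenome Dynamics for
    Bacterial Genome Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to delimit bacterial species from intergenomic
    distances and to characterise the resulting species clusters.
    Implements a GBDP-style fragment-match distance between genome
    assemblies with conversion to digital DNA-DNA hybridization (dDDH),
    query-based collection filtering, neighbour-joining phylogeny
    reconstruction, a species-delimitation scan over hierarchical
    clustering linkages and distance thresholds scored by the adjusted
    Rand index, pangenome rarefaction (core, pan and new-gene curves over
    random genome orderings), Faith's phylogenetic diversity with a
    tip-shuffling null model, presence scoring of multi-gene characters
    such as biosynthetic clusters, and synteny analysis of multi-gene
    genomic islands with flanking context. A seeded synthetic-genome
    generator with planted species structure provides ground truth for
    every stage, and a pipeline driver runs the stages end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    mclust,
    picante,
    tidyr,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
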