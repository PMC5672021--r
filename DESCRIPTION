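Package: plastome
Title: Plastome Architecture, Rearrangement and Phylogenetic Marker Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated circular plastid
    genomes: detection of the quadripartite LSC/IRa/SSC/IRb layout and
    single-copy/inverted-repeat junction context, signed gene-order
    comparison with inversion and breakpoint statistics, fragmentation of
    genomes into coding and non-coding regions with reference-based
    homology grouping, multiple alignment with conserved-block and
    outlier-sequence filtering, partition-scheme assembly, distance-based
    tree inference with bootstrap, Kendall-Colijn tree comparison, and
    standardized ranking of candidate phylogenetic markers. Includes a
    seeded synthetic-plastome generator that plants known inverted-repeat
    boundaries, rearrangements, pseudogenes and sequence divergence along
    a known species tree, so that every stage of the pipeline can be
    validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    stringi,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
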