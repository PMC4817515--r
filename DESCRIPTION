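Package: pancog
Title: Bacterial Pan-Genome Construction, Phylogenomics and Gene Gain/Loss Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for strain-level comparative genomics of bacterial species:
    all-vs-all protein similarity search with BLAST-like thresholds,
    bidirectional-best-hit orthology, Markov clustering (MCL) of the similarity
    graph into gene families, pan- and core-genome accumulation profiles with
    Heaps-law power fits and an open/closed verdict, fragment-based average
    nucleotide identity (ANI), distance-based core-genome and gene-content
    trees, Dollo-parsimony reconstruction of gene-family gain and loss, and a
    codon-usage atypicality screen for horizontally transferred genes. A
    seeded strain-pangenome simulator with complete ground truth (strain tree,
    family memberships, gain/loss events, alien genes) supports end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    data.table,
    igraph,
    jsonlite,
    Matrix,
    methods,
    phangorn,
    stats,
    utils,
    vegan
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
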