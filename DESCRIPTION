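Package: cyanotraits
Title: Comparative Phylogenomics of Lifestyle-Linked Traits and Biosynthetic
    Gene Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative phylogenomic analysis of lifestyle-linked
    molecular functions and biosynthetic gene clusters (BGCs) in bacterial
    genome collections, motivated by the study of host-associated cyanobacteria.
    Builds binary trait matrices from KEGG-ortholog annotations via declarative
    multi-step function definitions; groups BGC predictions by protein-domain
    composition with Sorensen-Dice similarity and Louvain community detection;
    fits phylogenetic logistic regression with Firth's penalised likelihood and
    phylogenetic linear regression under a Pagel's lambda covariance model, both
    with parametric bootstrap inference; measures phylogenetic signal of binary
    traits with the Fritz-Purvis D-statistic; and ships a synthetic-data
    generator that plants monophyletic host clades, lifestyle-linked traits and
    BGC group structure on simulated phylogenies so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Matrix,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    mclust,
    nlme,
    optparse
Config/testthat/edition: 3
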