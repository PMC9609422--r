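Package: netpharm
Title: Network Pharmacology Analysis of Drug Targets on Disease Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for network-pharmacology analyses of compound targets on
    disease protein-protein interaction (PPI) networks: confidence-filtered
    network construction from edge lists (TSV/SIF), degree/closeness/betweenness
    centrality with Cytoscape NetworkAnalyzer conventions, two-stage hub-gene
    selection by per-centrality ranking and intersection, a from-scratch
    implementation of the MCODE molecular-complex-detection algorithm with its
    density-times-size cluster score, identifier normalization with Venn
    intersection and coverage statistics for drug-disease target overlap, and
    one-sided hypergeometric over-representation analysis over GMT annotation
    sets. Includes seeded synthetic-data generators (scale-free backgrounds
    with planted dense modules, gene lists with controlled overlap, annotation
    collections with planted enrichment) so every stage is testable without
    database access, and a reproducible end-to-end pipeline driver.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
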