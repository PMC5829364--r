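Package: netpharm
Title: Network Pharmacology Analysis of Multi-Compound Herbal Remedies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A tested pipeline for network-pharmacology studies of
    multi-compound remedies: filtered ingestion of compound-target
    predictions, disease-gene association tables, and confidence-scored
    protein-protein interaction (PPI) edge lists; construction of
    compound-target bipartite networks, seed-anchored PPI neighbourhood
    networks, and merged compound-intersection-target networks; degree,
    betweenness, and closeness centralities with mean-threshold major-node
    (hub) selection; and hypergeometric overrepresentation analysis with
    Benjamini-Hochberg false discovery rate control, rich factors, and
    category tallies. Includes seeded synthetic-data generators that
    reproduce the structural shape such studies assume, plus SIF and
    GraphML exports for Cytoscape.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    tools,
    utils
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
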