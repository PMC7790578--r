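Package: netpharm
Title: Network Pharmacology Toolkit for Herb-Compound-Target-Disease Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for network-pharmacology analysis of multi-herb preparations:
    ADME screening of candidate compounds by oral bioavailability and
    drug-likeness, compound-target mapping and the target-set algebra behind
    herb-herb and drug-disease Venn overlaps, compound-target bipartite and
    protein-protein interaction network construction from STRING-style edge
    lists, six node-centrality measures (degree, betweenness, closeness,
    eigenvector, local average connectivity, network centrality) with
    median-consensus hub selection, maximal clique centrality (MCC) hub ranking
    via Bron-Kerbosch enumeration, hypergeometric over-representation analysis
    with Benjamini-Hochberg adjustment, and a synthetic-data generator with
    planted ground truth for closed-loop validation of every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
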