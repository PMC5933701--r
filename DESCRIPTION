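Package: evimap
Title: Evidence Maps of Causal Relations Between Biological Phenomena
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Build, score, merge, and query evidence maps: directed graphs
    in which nodes are biological phenomena (identified by What/Where/When
    text properties) and edges aggregate empirical experiments and
    hypothetical assertions about causal relations. Each empirical edge is
    scored with a Bayesian calculus based on Dirichlet-multinomial posterior
    means with Laplace smoothing, expressing the convergence of evidence
    across the four connection-experiment classes (positive/negative
    intervention and non-intervention) and the consistency of evidence
    within each class. Includes multi-map aggregation with per-edge
    provenance, filtered neighborhood queries, structural conflict detection
    between signed causal pathways and independence findings, JSON/CSV/DOT/
    GraphML interchange, a seeded synthetic-map generator, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
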