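Package: pathalign
Title: Pairwise Alignment of Metabolic Pathways as Directed Hypergraphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pairwise comparison and alignment of metabolic pathways
    represented as directed hypergraphs (compounds as nodes, reactions as
    hyperedges). Computes a reaction similarity score combining hierarchical
    EC-number similarity with compound-set similarity obtained by
    maximum-weight bipartite matching, aligns maximal reaction paths with a
    Smith-Waterman local alignment, derives a one-to-one reaction matching
    from the match-frequency matrix, and reports a pathway similarity score
    together with the largest conserved subpathway. Includes multi-pathway
    comparative analyses (average organism scores, distance matrices,
    hierarchical clustering export, cluster motif intersection), readers for
    KGML and a plain JSON pathway format, and a seeded synthetic-pathway
    generator for testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    xml2,
    ape,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
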