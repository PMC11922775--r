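Package: degnet
Title: Differential-Expression-Enriched Pathway Networks, Node-Removal
    Centrality and Ciliary-Targeting Motif Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds bipartite gene-pathway networks from pathway gene sets
    (GMT) and differential-expression tables, restricted to significant
    features.  Ranks genes by the drop in global efficiency caused by their
    removal, runs ordered-query hypergeometric enrichment on the central
    genes, and prioritizes pathways against a designated anchor pathway
    with a combined coefficient blending impact similarity, connection
    strength and a key-regulator (eigenvector-centrality) index.  Extracts
    minimum-node-distance chains between a gene set and the anchor, scans
    the importance-ordered gene list for zones of coordinated up- or
    down-regulation with a +/-1 cumulative score, and scans protein
    sequences for VxPx ciliary-targeting motifs with a mutation planner.
    Includes a seeded synthetic-data generator with planted ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
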