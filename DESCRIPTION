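Package: ctpflow
Title: Compound-Target-Pathogenic-Gene Network Screening for Multi-Herb Formulas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Systems-pharmacology screening of multi-herb prescriptions.
    Filters candidate compounds with rule-based ADMET and physicochemical
    criteria, assembles a tripartite compound-target-pathogenic-gene network
    from compound-target predictions, disease gene lists and protein-protein
    interactions, scores target genes with a scalarized multi-objective model
    (with degree, closeness and betweenness centrality baselines), propagates
    interaction-intensity flow onto pathogenic genes, compounds and pathways,
    and selects the minimal compound combination covering a set fraction of
    the total intensity. Includes hypergeometric gene-set enrichment, a simple
    two-group differential-expression summary, and a seeded synthetic-data
    generator with planted ground truth for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
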