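Package: lnccan
Title: Stratified lncRNA Coherent Association Networks from Bipartite
    Co-Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers competing-endogenous-RNA (ceRNA) modulation networks
    from subtype-stratified expression cohorts. From mRNA, lncRNA and
    miRNA expression matrices it builds Fisher-z tables of Spearman
    correlations, selects |z| cutoffs by the scale-free topology
    criterion, constructs bipartite cross-class co-expression networks,
    scores same-class node pairs with five interaction-profile
    association indices (Jaccard, Simpson, geometric, cosine,
    profile-PCC) in two bipartite contexts, selects coherent lncRNA
    associations by multi-index consensus, detects network modules, and
    characterizes them with PPI overlap, GO semantic similarity
    (simRel/funSim) and hypergeometric enrichment. Ships a seeded
    synthetic-cohort generator with planted ceRNA groups, a toy ontology
    and a toy PPI list so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
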