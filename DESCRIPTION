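Package: cernet
Title: Competing Endogenous RNA Network Inference from Paired Expression
    and miRNA Interaction Data
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers lncRNA-mRNA competing endogenous RNA (ceRNA) networks
    from paired tumor/normal expression profiles and bipartite
    miRNA-target interaction tables. Provides probe re-annotation
    filtering, paired SAM-style permutation differential expression,
    hypergeometric scoring of shared-miRNA lncRNA-mRNA pairs with FDR
    control, centrality-based and random-walk-with-restart candidate
    prioritization, Pearson co-expression screening with ceRNA module
    extraction, and a synthetic-data generator with planted ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
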