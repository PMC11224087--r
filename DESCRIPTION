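Package: cernet
Title: Competing Endogenous RNA Network Inference from Two-Group Expression Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers lncRNA- and circRNA-associated competing endogenous RNA
    (ceRNA) regulatory networks from two-group microarray intensity data.
    Provides quantile normalization and differential expression screening
    (fold change plus t-test), a canonical miRNA seed-match target scanner
    with an importer for external prediction tables, signed Pearson
    co-expression filtering, a hypergeometric shared-miRNA ceRNA-pair score,
    tripartite network assembly with SIF/GraphML export, maximal-clique
    centrality (MCC) hub ranking on protein-protein interaction graphs,
    generic over-representation analysis against GMT gene sets, and
    2^-ddCt qPCR quantification. A synthetic-data generator plants known
    sponge-miRNA-mRNA triplets so the whole pipeline is testable end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    limma,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
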