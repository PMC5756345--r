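Package: pandriver
Title: Multiplex Network and Pathway Based Detection of Cancer Driver Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate driver genes by integrating functional
    pathways with multiplex gene-gene interaction networks. For every gene in
    a pathway the package computes its degree centrality in each interaction
    layer, its degree restricted to pathway co-members, and the degree
    expected under an equal edge-probability null; genes whose
    pathway-restricted centrality exceeds expectation in at least two layers
    are called network drivers. Downstream stages intersect drivers with
    differentially expressed genes (tumour versus normal), summarise
    cross-condition sharing and benchmark overlaps, and rank driver genes by
    cross-validated random-forest AUC. A synthetic-data module generates
    fully self-contained study bundles (pathways, multiplex layers with
    planted pathway-dense drivers, negative-binomial counts with planted
    fold changes) with ground truth for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    randomForest,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
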