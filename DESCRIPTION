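Package: crossneuro
Title: Cross-Species Conservation Analysis of GABAergic Neuron Single-Cell Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for comparing inhibitory (GABAergic) neuron cell types
    across mammalian species from single-nucleus RNA-seq counts: one-to-one
    ortholog mapping, log-normalisation, reciprocal-PCA anchor integration and
    graph clustering, a cluster-overlap conservation score between subtypes,
    supervised MetaNeighbor-style neighbor-voting AUROC for gene sets,
    pseudocell aggregation with topological-overlap co-expression modules and
    hypergeometric risk-gene enrichment, Wilcoxon differential expression, and
    AUCell-style regulon activity scoring with bimodal binarisation and k-means
    grouping of activation profiles. Includes a negative-binomial multi-species
    simulator with planted cell types, batch effects, co-expression modules,
    regulons and a disease condition, so every stage can be validated against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    mclust,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
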