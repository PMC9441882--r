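Package: redisx
Title: Patient Stratification by Continuous Max-Flow Graph Cuts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Semi-supervised stratification of patient cohorts from gene
    expression profiles. Samples are pre-labelled by agglomerative
    hierarchical clustering, and the labels are refined by a continuous
    max-flow (CMF) multiclass min-cut on a cosine K-nearest-neighbour
    similarity graph, with region forces derived from m-step diffusion
    connectivity to cluster seeds. Because the graph cut merges clusters
    that the data do not support, the number of subpopulations is selected
    as the modal count of surviving clusters over requested k = 1..20.
    Downstream stages score per-cluster differential expression against
    controls with cross-cluster overlap exclusion, and rank hub genes on a
    supplied interaction network by Maximal Clique Centrality. A planted
    structure synthetic expression generator supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    limma,
    mclust,
    Rtsne,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
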