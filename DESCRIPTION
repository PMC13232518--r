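Package: egnet
Title: Enhancer-Gene Interaction Prediction and Regulatory Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts enhancer-gene (E-G) regulatory interactions from
    chromatin accessibility, histone acetylation, 3D contact and
    sequence-derived activity features, and analyses the resulting
    regulatory networks. Builds candidate cis-regulatory elements (CREs)
    from DNase-seq peaks, enumerates candidate E-G pairs within a distance
    window, computes activity-by-contact scores, trains an L2-regularised
    logistic classifier on CRISPRi-labelled pairs, and benchmarks
    predictions with precision-recall statistics and bootstrap confidence
    intervals. Downstream network tools include bipartite community
    detection with redundant/non-redundant substructure classification,
    matched-background permutation tests for variant and eQTL enrichment,
    and motif / gene-set enrichment statistics. A seeded simulation module
    generates complete synthetic input sets with planted regulatory
    structure for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr,
    optparse
Config/testthat/edition: 3
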