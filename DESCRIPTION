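Package: drwgo
Title: Downward Random Walks for Predicting Missing Gene Ontology
    Annotations
Version: 0.1.0
Authors@R:
    person("drwgo", "maintainers", email = "drwgo@example.org",
           role = c("aut", "cre"))
Description: Predicts missing Gene Ontology (GO) annotations of partially
    annotated proteins with downward random walks with restart on the GO
    directed acyclic graph (dRW), optionally fused with a k-nearest-neighbour
    classifier over annotation-derived protein semantic similarity (dRW-kNN).
    Includes Lin similarity with structure- and corpus-based information
    content, frequency (Naive) and neighbour-annotation (ITSS-style)
    baselines, multi-label evaluation metrics (MacroF1, AvgROC, 1-RankLoss,
    RAccuracy, Fmax, Coverage, stratified per-term AUC), a leaf-masking
    experiment protocol, a historical-rollback comparison, OBO/GAF readers
    and writers, and a synthetic ontology and annotation generator for fully
    offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
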