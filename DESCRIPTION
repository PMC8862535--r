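Package: kidclass
Title: Hierarchical Probabilistic Cell-Type Classification for Developing Kidney scRNA-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trainable tiered classification of single-cell RNA-seq profiles
    against a fixed developing-kidney identity tree. A radial-kernel support
    vector machine with Platt-calibrated one-vs-rest probabilities is trained
    at every internal node of the tree in its own PCA feature space (with an
    optional single round of batch harmonization); queries are classified
    top-down with a rejection threshold at the first tier, marker-gated
    refinement of nephron progenitor calls into an NPC-like class, AUROC/AUPRC
    threshold-calibration diagnostics, and cross-sample composition and
    gene-summary comparison tables. Includes a hierarchical negative-binomial
    count simulator so the full pipeline is trainable and testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    e1071,
    igraph,
    jsonlite,
    nnet,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
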