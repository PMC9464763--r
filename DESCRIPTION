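Package: modalign
Title: Unsupervised Integration of Single-Cell Chromatin Accessibility and
    Gene Expression via Contrastive and Cycle-Consistent Adversarial Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Learns one joint 128-dimensional representation for unpaired
    single-cell RNA-seq and scATAC-seq gene-activity matrices. An encoder
    shared by both modalities is trained with a noise-contrastive (NCE)
    loss on augmented views, an adversarial domain loss that removes the
    modality difference in the latent space, and a cycle-consistent
    adversarial branch in which a generator maps RNA-derived latent codes
    to accessibility-like data that must re-encode to the same code.
    Includes preprocessing (log1p normalisation, dispersion-based highly
    variable gene selection, feature harmonisation), a synthetic
    dual-modality data generator, the integration benchmark metrics
    (modality and cell-type silhouettes on a 2-D UMAP, bidirectional SVM
    label-transfer macro F1, weighted aggregation and Wilcoxon-based
    ranking), and post-integration utilities (cross-modal label and
    expression prediction, velocity layer assembly).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    cluster,
    dplyr,
    e1071,
    ggplot2,
    jsonlite,
    methods,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    uwot
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
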