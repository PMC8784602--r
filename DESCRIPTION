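Package: embscope
Title: Interpretable Convolutional Classification of Endomyocardial Biopsy Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete pipeline for heart-failure detection from H&E-stained
    endomyocardial biopsy (EMB) regions of interest: a global-average-pooling
    (GAP) headed convolutional classifier trained with cross-entropy and Adam,
    gradient-weighted class activation mapping (Grad-CAM) for regional
    interpretability, UMAP embedding of deep features for feature-space
    visualization, a C(K,m) multi-model ensemble built on case-level
    cross-validation folds, and ROI-to-case risk aggregation with ROC/AUC
    reporting. Includes a synthetic H&E-like image generator with planted
    failure morphology (enlarged nuclei, infiltration-like clusters,
    vacuolation) and ground-truth lesion masks, so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    utils,
    uwot,
    yaml
Suggests:
    cluster,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
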