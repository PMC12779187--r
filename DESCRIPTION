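Package: orthofusion
Title: Multimodal Feature Extraction and Fusion Classification for
    Orthodontic Extraction Decisions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Geometric feature extraction from segmented dental arches
    (standard arch measurements plus centroid-to-arch-center and
    centroid-to-Bezier distances), deterministic preprocessing of lateral
    cephalogram images, pairwise angular featurisation of cephalometric
    landmarks, a fully convolutional autoencoder with spatial attention
    and spatial pyramid pooling, and a nested cross-validated,
    Bayesian-tuned fusion classifier with majority-vote ensembling and
    paired diagnostic evaluation (confusion-matrix metrics, likelihood
    ratios, McNemar tests). Includes a seeded synthetic-cohort generator
    emulating two-class arch geometries, landmark configurations and
    radiograph-like images for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    EBImage,
    e1071,
    glmnet,
    randomForest,
    rpart,
    lhs,
    png,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
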