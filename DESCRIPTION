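Package: BFProfiler
Title: Discrimination of Single-Gene Mutants from Bright-Field Cell Image
    Texture Profiles
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for label-free single-cell morphological profiling from
    paired bright-field and nuclear-stain microscopy images. The package
    generates ground-truthed synthetic image populations, detects nuclei and
    crops cellular regions, quantifies a fixed 296-dimensional texture
    profile per cell built around multi-threshold dark-clump morphology,
    standardizes features against a wild-type reference with outlier
    removal and clone pooling, discriminates mutant from wild-type cells
    with L1-regularized logistic regression under nested tenfold
    cross-validation (ROC/AUC, per-feature rank tests, learning curves),
    and clusters mutants by the similarity of their regression-coefficient
    profiles to recover functionally related gene pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp,
    jsonlite,
    tiff,
    png,
    ape,
    yaml,
    withr,
    pheatmap,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
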