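Package: fishpheno
Title: Spatial Phenotyping of Single-Molecule FISH Images and Extracellular
    Vesicle miRNA Biomarker Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the subcellular distribution of single-molecule FISH
    (smFISH) spots in segmented cells and classifies cell disease state from
    the resulting spatial features. Provides a ground-truthed synthetic image
    and cohort generator, Laplacian-of-Gaussian spot detection with
    nucleus/cytoplasm assignment, per-cell feature extraction (expression,
    location, Ripley K/L/H clustering and nuclear-boundary aggregation),
    supervised pairwise classification with ROC comparison across feature
    sets, and a biomarker-panel stage with multi-algorithm ensemble feature
    ranking, group comparisons, differential-expression filtering and
    bias-corrected cross-validated AUC with bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    class,
    e1071,
    grDevices,
    graphics,
    jsonlite,
    randomForest,
    rpart,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
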