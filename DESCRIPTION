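Package: tsrscore
Title: Tumor-Stroma Ratio Scoring from Tissue-Class Segmentation Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Semi- and fully automated scoring of the tumor-stroma ratio
    (TSR) in colorectal cancer histopathology, operating on pixel-level
    tissue-class label maps produced by an upstream segmentation model.
    Implements hot-spot TSR computation inside a circular field of view,
    tumor-bulk extraction by morphological post-processing, a
    Fourier-domain sliding-window TSR heatmap with tissue-composition
    validity rules and top-k hot-spot ranking, and the observer-agreement
    statistics used to compare scoring methods (Cohen's kappa, ICC(2,1)
    with confidence interval, tie-aware Spearman correlation,
    Bland-Altman limits of agreement, t-tests). A synthetic label-map and
    rater-score generator with analytic ground truth makes every stage
    testable without slide data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
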