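Package: histocorr
Title: Weakly Supervised Region-Correlation Classification of Whole-Slide
    Histology Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-stage weakly supervised pipeline for predicting a binary
    slide-level molecular label (such as nuclear BAP1 expression in uveal
    melanoma) from H&E-stained whole-slide images. Slides are tiled into
    tumor patches (>90% tumor content), patches inherit the slide label,
    and a residual convolutional network is trained with class-weighted
    cross-entropy. Patch feature vectors are reassembled into per-slide
    global feature maps and refined by a U-Net style encoder-decoder that
    exploits spatial correlation between neighboring tumor regions, with a
    tumor-mask-gated loss. Includes slide-level aggregation, K-fold
    cross-validation with slide-level splits, model ensembling, ROC/AUC
    evaluation with bootstrap confidence intervals, probability-map
    rendering, and a seeded synthetic slide generator for end-to-end
    testing without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    png,
    yaml,
    stats,
    tools,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pROC,
    EBImage,
    jsonlite
Config/testthat/edition: 3
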