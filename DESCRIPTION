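Package: slimscreen
Title: Label-Free Colorectal Cancer Screening on Quantitative Phase Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Automated colorectal cancer screening on quantitative phase
    images of tissue microarray cores acquired by spatial light interference
    microscopy (SLIM). Provides forward simulation and four-frame
    phase-shifting retrieval of SLIM phase maps, mosaic tile stitching,
    synthetic tissue-core generation with ground-truth gland instances,
    gland instance detection and classification (a deterministic
    morphological segmenter and a compact trainable two-stage detector),
    core-level diagnosis by gland-vote thresholding, and instance-detection
    evaluation: confusion matrices, per-class precision/recall/F1 reports,
    detection-confidence sweeps, and ROC/AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
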