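Package: eapiou
Title: Aspect-Ratio-Penalized IoU Losses, Spatial Squeeze-and-Excitation
    Attention, and Detection Evaluation for Nodule Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the explicit aspect-ratio-penalty IoU (EAPIoU)
    bounding-box score and loss together with the GIoU, DIoU and CIoU
    baselines it extends, with exact analytic gradients for simulated
    box regression; a reference forward computation of a spatial
    squeeze-and-excitation (SSE) attention module (channel
    squeeze-and-excitation followed by a max/average-pooled spatial
    attention map); object-detection evaluation (greedy matching,
    precision/recall curves, average precision, mAP@50 and mAP@50-90);
    a seeded gradient-descent box-regression simulator for comparing
    loss variants and penalty weights; and seeded synthetic-data
    generators (box pairs with controlled overlap and aspect-ratio
    mismatch, CT-slice-like nodule scenes with tight box labels,
    random feature maps, corrupted predictions). All results are
    tibbles designed for pipe-based workflows, with ggplot2 autoplot()
    methods and broom-style tidy()/glance() accessors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    png,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
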