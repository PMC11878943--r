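Package: foalwatch
Title: Desk-Scale Detection of Mare Parturition from Stable Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting mare parturition (foaling) in stable
    camera footage at desk scale. Implements the data-curation pipeline
    (frame striding, SSIM deduplication, resizing, 2:1 splitting,
    occlusion/contrast/blur augmentation, COCO JSON I/O), the neural
    operators of a two-stage detector (residual blocks, CBAM/SE/GCA
    attention gates, CARAFE content-aware upsampling, a balanced feature
    pyramid, generic multi-level RoI extraction, IoU-balanced sampling and
    the balanced L1 loss), COCO-style evaluation (AP with 11-point and
    area interpolation, mAP over IoU 0.50:0.05:0.95, average recall), and
    a sliding-window alert layer over per-second frame labels. A synthetic
    scene and frame-label-stream generator makes every stage testable
    without farm data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
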