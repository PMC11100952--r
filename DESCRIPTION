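Package: fetseg
Title: Fetal Head Ultrasound Segmentation Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Building blocks for prompt-based multi-class segmentation of
    fetal head ultrasound images: a seeded phantom generator emulating the
    four-class anatomy (background, fetal brain, cavum septum pellucidum,
    lateral ventricles), a nine-strategy joint image/mask augmentation
    pipeline, inverse-frequency class-weight calculation with range
    smoothing, weighted Dice and Lovasz segmentation losses and their
    convex combination, per-class prompt bounding-box derivation from
    one-hot masks, DSC/Hausdorff/average-surface-distance evaluation, and
    a CPU-scale training harness with a pluggable segmenter interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
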