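Package: RelPoolSeg
Title: Brain Tumor Segmentation with a Related 3D Pooling U-Net
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Volumetric segmentation of glioma sub-regions from multi-modal
    MRI with a 3D U-Net whose down-sampling stages use Related 3D Pooling, a
    fixed weighted aggregation over each 2x2x2 window that preserves
    inter-voxel relationships lost by max pooling. Provides the two training
    pipelines (min-max percentile and z-score normalization with matched
    augmentation policies), a natively implemented encoder-decoder network
    with group normalization and transposed-convolution up-sampling, the soft
    Dice loss, Dice/sensitivity/specificity/HD95 evaluation metrics, snapshot
    ensembling by probability averaging, BraTS-convention label
    reconstruction, and a synthetic phantom generator so that every stage is
    testable without any dataset download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
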