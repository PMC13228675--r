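Package: synovol
Title: Synovial Tissue Volume Estimation from 3D Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic estimation of synovial tissue volume (STV) from 3D
    ultrasound of the first carpometacarpal (CMC1) joint. Provides volume and
    label I/O (NIfTI, MetaImage), region-of-interest cropping and transverse
    reslicing, a seeded synthetic speckle-phantom generator with a simulated
    second rater, compact trainable 2D U-Net and U-Net++ slice segmenters
    written in vectorized base R, contour-stitched watertight surface
    reconstruction with enclosed-volume computation, a full segmentation
    evaluation battery (Dice, precision, recall, accuracy, mean surface and
    Hausdorff distances with signed variants, area/volume percent difference),
    and normality-gated paired statistics with Bland-Altman agreement analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    EBImage,
    jsonlite,
    png,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
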