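Package: ada3d
Title: Adaptive Discriminator Augmentation and Evaluation Toolkit for
    Volumetric Medical Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for training-time adaptive discriminator augmentation
    (ADA) of three-dimensional grayscale volumes such as lung-nodule CT
    crops. Provides a voxel-volume data model with NPZ and NIfTI input
    and output, the full volumetric augmentation pipeline (pixel-level,
    geometric, colour, frequency-band filtering and corruption
    transforms, each gated by a shared probability), the adaptive
    probability controller driven by the discriminator's positive rate,
    depth-aware R1 and path-length regularizers defined against a
    differentiable-network contract, 3D structural similarity and
    kernel-distance (polynomial-kernel MMD) metrics with moving-average
    snapshot selection, and a synthetic nodule-volume generator for
    fully reproducible desk-scale experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    graphics,
    utils,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
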