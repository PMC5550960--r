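Package: sparseTFM
Title: Regularized Traction Force Microscopy in the Spatial Domain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Recovers cell-exerted traction fields from substrate
    displacement fields measured in two-dimensional Traction Force
    Microscopy (TFM) experiments. Implements the discrete Boussinesq
    forward model for a semi-infinite elastic substrate and four
    regularized inverse solvers: zero-order Tikhonov (L2) regularization
    in the Fourier and spatial domains, L1 (sparsity-promoting)
    regularization, and full-L1 regularization (L1 norms on both the data
    fidelity and penalty terms), the latter two solved by iteratively
    reweighted least squares. A stiffness-matrix reduction based on Otsu
    segmentation of the displacement magnitude makes whole-cell spatial
    domain recovery tractable on a desktop computer. Ships a synthetic
    benchmark generator (sparse stress footprints, forward displacements,
    additive noise), multilevel isodata footprint segmentation, and a
    suite of error metrics to validate and compare the schemes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
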