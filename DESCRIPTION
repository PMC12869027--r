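Package: qpat
Title: Quantitative Photoacoustic Tomography with Integrated Spectral and
    Depth Compensation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of oxygen saturation and total hemoglobin maps from
    multispectral beamformed photoacoustic pressure images. Implements linear
    unmixing (LU), convex-cone (CC) angular-distance estimation, and
    compensated linear unmixing (CLU) corrected for wavelength-dependent
    fluence (spectral coloring) with an average fluence spectrum derived from
    Monte-Carlo photon transport, plus depth-wise exponential compensation for
    optical and acoustic attenuation (the integrated spectral and depth
    compensation, ISDC, pipeline). Ships a seedable 2-D voxel Monte-Carlo
    photon transport engine, digital-phantom builders (depth-varying sulfate
    tube phantoms, ovary-mimicking sphere, clinical layered medium) with a
    forward pressure model, cluster-wise evaluation utilities (uniformity
    standard deviation, total-hemoglobin ratio, compensator ranking), and
    lesion classification by logistic regression with ROC analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    cluster,
    jsonlite,
    pROC,
    pracma,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
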