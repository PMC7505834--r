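Package: octarep
Title: Repeatability Analysis of OCTA Binarization Thresholding and
    Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to study the repeatability of quantification metrics
    derived from en-face optical coherence tomography angiography (OCTA)
    images. Implements the eleven global and local binarization
    thresholding algorithms used across the OCTA literature (Default,
    Huang, IsoData, mean, Otsu; Bernsen, local mean, local median,
    Niblack, local Otsu, Phansalkar), contrast and image processing
    steps (pointwise contrast gain about mid-gray, histogram
    normalization with saturation, contrast-limited adaptive histogram
    equalization, rigid registration), vessel area density, skeleton
    vessel length and choriocapillaris flow-deficit metrics, and
    intraclass correlation coefficient (ICC) estimators (one-way random,
    two-way mixed) with high/low repeatability classification. A
    synthetic phantom generator emulates repeat acquisitions of retinal
    plexus and choriocapillaris angiograms so the full factorial
    experiment (cohort x processing x threshold x metric x ICC) can be
    run and tested without patient images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    png,
    tiff,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
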