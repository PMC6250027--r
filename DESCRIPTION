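Package: PleuraCAD
Title: Detection of Malignant Cells in Cytological Pleural Effusion Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end computer-aided diagnosis pipeline for cytological
    pleural effusion (CPE) microscopy: hybrid SLIC-superpixel/K-Means nuclei
    segmentation in L*a*b* space, multiscale morphological refinement,
    SVM-gated splitting of overlapping nuclei via contour concavity analysis
    and direct least-squares ellipse fitting, a 201-dimensional
    morphometric/colorimetric/textural (FOS, GLCM, GLRLM) feature extractor,
    simulated-annealing feature selection scored by a small feedforward
    network, and a bagged decision-tree ensemble classifier. Ships a synthetic
    CPE scene generator with per-nucleus ground truth so the full pipeline is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    tools,
    Rcpp,
    EBImage,
    e1071,
    nnet,
    rpart,
    png,
    tiff,
    yaml,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
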