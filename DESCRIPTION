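Package: airDIC
Title: Incremental Digital Image Correlation and Biomechanical Screening for
    Air-Puff Corneal Image Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Turns high-speed image sequences of a corneal cross-section under
    an air puff into full-field displacement, Cauchy strain, velocity and
    strain-rate histories using incremental subset-based digital image
    correlation (DIC) with subpixel refinement. Reduces the field histories to
    eight evolution curves (maximum and average of vertical displacement,
    shear strain, vertical velocity and shear strain rate over time), and
    feeds them to Naive Bayes, Random Forest, soft-voting ensemble and
    ridge-logistic classifiers to screen for forme fruste keratoconus.
    Includes a synthetic speckle-sequence simulator with analytic ground
    truth for validation, confusion-matrix and ROC evaluation utilities, and
    a command-line pipeline chaining all stages.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    tiff,
    jsonlite,
    pROC,
    randomForest,
    e1071,
    glmnet,
    optparse,
    withr,
    rlang,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
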