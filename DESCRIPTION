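Package: xylovision
Title: Computational Wood Anatomy from Transverse-Section Micrographs
Version: 0.1.0
Authors@R:
    person("Xylovision", "Developers", email = "xylovision@example.org",
           role = c("aut", "cre"))
Description: A pipeline for quantitative wood anatomy on transverse-section
    micrographs: scale-invariant keypoint (SIFT) bag-of-descriptor shape
    features, connected-component pore-size log-log histogram features,
    Fisher linear discriminant reduction, species classification with
    k-nearest-neighbour, multinomial logistic and linear support-vector
    classifiers under repeated stratified splits, Ward hierarchical
    clustering of images and taxa, and a k-means visual-word atlas of
    keypoints.  Includes a synthetic micrograph generator that emulates
    ring-porous, diffuse-porous and radial-porous hardwood sections with
    ground-truth pore masks, so the whole pipeline is testable without
    proprietary image collections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    glmnet,
    ape,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite
Config/testthat/edition: 3
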