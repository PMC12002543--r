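Package: vera
Title: Semi-Automated Quantification of Entheseal Changes on 3D Bone
    Surface Meshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects and measures projecting surface irregularities
    ("entheseal changes") on triangle meshes of bones. Provides mesh
    input/output for PLY, OBJ and STL, resolution checking and isotropic
    remeshing, principal-curvature estimation by local quadric fitting,
    rank-based histogram equalization of the minimum-curvature field,
    threshold segmentation with small-component removal, and 3D surface
    area measurement in square millimetres. Includes a deterministic
    synthetic bone-phantom generator with bump ground truth for end-to-end
    validation, and the repeatability and group-comparison statistics used
    to validate such measurements (Lin's concordance correlation
    coefficient, MANOVA with Pillai's trace, PCA, regression/ANCOVA,
    Spearman screening).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
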