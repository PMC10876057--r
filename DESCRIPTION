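Package: chestshape
Title: Depth-Camera Quantification of Chest-Wall Shape
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-ionizing quantification of chest-wall shape from depth-camera
    recordings. Depth frames from a bedside depth camera are deprojected into
    triangulated 3D chest surfaces on which straight-line (Euclidean) and
    on-surface (geodesic) distances between upper- and lower-chest landmarks
    are measured; the upper/lower distance ratio (bell-shape index) flags the
    bell-shaped chest configuration seen in spinal muscular atrophy. Includes
    a chest-radiograph comparator (2D rib-edge distances), small-sample
    nonparametric group statistics (exact Mann-Whitney U, Fisher exact), and
    a parametric supine-torso simulator with known ground-truth distances so
    the entire pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    png,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE, load = "source")
RoxygenNote: 7.3.3
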