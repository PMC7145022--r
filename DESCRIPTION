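Package: craniomorph
Title: Craniofacial Shape Analysis with TPS Warping and Sliding Semi-Landmarks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Geometric-morphometric analysis of 3D head surface meshes.
    Builds a 500-point template (20 anchor anatomical landmarks plus 480
    surface semi-landmarks), transfers it to target meshes by 3D thin-plate
    spline warping with closest-point projection, relaxes the semi-landmarks
    by bending-energy-minimizing tangent sliding, and runs the downstream
    statistical battery: generalized Procrustes analysis, hierarchical
    Procrustes ANOVA with digitization error, principal components with
    parallel-analysis retention, Euclidean distance matrix analysis,
    allometric regression, MANOVA slope/intercept tests, canonical variate
    ordination and cross-validated discriminant classification. A synthetic
    head-mesh generator with known group effects, allometry and digitization
    noise makes every stage testable without restricted scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
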