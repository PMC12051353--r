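Package: dmdgait
Title: Predictive Planar Gait Simulation for Duchenne Muscular Dystrophy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Personalizes Hill-type planar musculoskeletal models with
    Duchenne muscular dystrophy (DMD) specific muscle weakness, contractures,
    altered anthropometry and foot deformities from clinical-measurement
    tables, generates predictive gait simulations by direct-collocation
    trajectory optimization on a reduced sagittal-plane model, and quantifies
    simulated DMD-versus-typically-developing gait deviations across a
    mean and plus/minus one standard deviation severity sweep. Includes a
    synthetic-cohort generator emulating the statistical structure of
    clinical strength, range-of-motion and stiffness measurements in three
    DMD gait-pattern groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
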