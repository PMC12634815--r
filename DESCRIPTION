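Package: csfmix
Title: Pulsatile Cerebrospinal Fluid Flow and Mixing in the Cerebral Aqueduct
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying pulsatile cerebrospinal fluid (CSF) flow through
    the cerebral aqueduct with idealized ventricle geometries. Generates
    synthetic subject cohorts with MRI-style flow descriptors (stroke volume,
    area-averaged velocity, Reynolds number), builds labeled tetrahedral
    meshes of parametric ventricle-aqueduct geometries, solves the
    incompressible Navier-Stokes equations with a stabilized P1/P1
    fractional-step finite element method driven by a moving lateral-ventricle
    wall, advects massless tracers through the periodic velocity field, and
    quantifies inter-ventricular exchange with a multiscale particle mix-norm.
    Includes nonparametric cohort statistics (Mann-Whitney U, inverse
    diameter-velocity regression, quartile outlier flagging).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
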