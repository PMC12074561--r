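Package: tips3d
Title: 3D Stent-Graft Geometry Measurement and Outcome Modelling for
    Transjugular Intrahepatic Portosystemic Shunts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Semiautomated measurement of the three-dimensional geometry of
    transjugular intrahepatic portosystemic shunt (TIPS) stent grafts from
    labelled CT-like volumes: medial centerline extraction between
    user-supplied seed points, multiplanar cross-sections orthogonal to the
    path, and seven geometry parameters including the maximum sectional
    stent curvature (angle between 1 cm chords separated by a 5 mm gap,
    maximised over the stent). Includes a parametric tubular phantom
    generator with analytic ground truth for validation, and the
    accompanying cohort statistics stage: nonparametric group comparisons,
    uni- and multivariate Cox proportional-hazards modelling with forward
    stepwise selection, a time-to-CT sensitivity model, and a survival-data
    simulator for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    RNifti,
    stats,
    survival,
    tibble,
    tidyr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
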