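Package: fiducialign
Title: Intra-Extraoral Registration with Tray-Mounted Fiducial Geometries
Version: 0.1.0
Authors@R: person("fiducialign", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A radiation-free digital workflow for registering the intraoral
    dentoalveolar arch position to an extraoral 3D facial surface scan using
    fiducial geometries (sphere or cross) mounted on a modified impression
    tray. Provides parametric fiducial marker generation with STL input and
    output, a virtual structured-light scanner with synthetic face and
    dental-arch surrogates, landmark-seeded rigid registration (Kabsch and
    iterative closest point), surface-deviation RMSE analysis, and exact
    rank-based statistics (Wilcoxon signed-rank, Mann-Whitney) for comparing
    marker designs. All geometry is in millimetres.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
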