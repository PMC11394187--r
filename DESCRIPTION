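Package: stentcheck
Title: Ureteral Stent Encrustation Detection from CT by 3D Morphological Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects encrustation on indwelling ureteral (double-J) stents in CT
    volumes. Given a CT volume and a stent segmentation (a Hounsfield-threshold
    baseline is included; masks from any external model can be imported), the
    pipeline fills axial gaps, isolates the stent by 3D connected-component
    filtering, thins it to a centerline, fits a B-spline and re-slices the stent
    perpendicular to its axis, profiles each cross-section in polar coordinates,
    and classifies radial anomalies as residual stone or encrustation. A seeded
    synthetic phantom generator with exact ground truth makes every stage
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
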