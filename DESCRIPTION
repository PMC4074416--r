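Package: nephroplan
Title: Virtual Resection-Plane Planning for Partial Nephrectomy from 3D CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning laparoscopic partial nephrectomy from
    contrast-enhanced (delay-phase) 3D CT volumes. Provides interactive-style
    segmentation of the kidney (graph-cut with scribble constraints), the
    urinary tract (seeded region growing above a CT-value threshold), and the
    tumor (smooth implicit surface fitted through planar contours); an
    anisotropic exact Euclidean distance transform; watertight surface
    extraction with CT-value sampling on vertices; and a resection planner
    that builds virtual resection regions at a schedule of surgical margins,
    predicts whether and where the urinary tract would be opened, and reports
    the minimum opening margin. A synthetic CT phantom generator with known
    analytic geometry makes the whole pipeline testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
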