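Package: enamelmap
Title: Morphologically Anchored Dental Enamel Thickness Measurement on 3D
    Tooth Crown Meshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Measures dental enamel thickness on triangulated surface models
    of tooth crowns, as reconstructed from micro-focus computed tomography.
    Segments an enamel-cap mesh into the outer enamel surface and the
    enamel-dentine junction from point positions and normal directions,
    orients the crown in its own coordinate system from the cervical edge,
    delineates the occlusal contour, builds the mesio-distal midline from a
    bucco-lingual section series, segments the occlusal enamel into buccal
    and lingual inner-slope sectors, and reports modified sector average
    enamel thickness in 3D (SAET3D) and 2D (SAET2D) together with per-vertex
    topographic thickness maps. Includes STL/PLY/OBJ mesh input and output,
    mesh validation and hole filling, and a synthetic-tooth generator with
    analytic ground truth for testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    grDevices,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
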