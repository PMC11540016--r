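Package: latticeqa
Title: Lattice Radiotherapy Planning Aid and Polymer-Gel CBCT Dosimetric Verification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for spatially fractionated lattice radiotherapy (LRT) quality
    assurance. Places sphere vertices on a hexagonal close-packed or rectangular
    lattice fully contained inside a target structure, and implements a complete
    polymer-gel dosimetry readout chain for cone-beam CT (CBCT) imaging: scan
    averaging and background subtraction, adaptive mean filtering, remnant ring
    artefact removal, hyperbolic-tangent dose-response self-calibration, and
    inversion to a 3D dose volume. Dose comparison utilities include line
    profiles, peak/valley metrics, isodose masks, per-vertex equivalent
    diameters, and 3D global gamma analysis with criterion sweeps. A synthetic
    phantom generator emulates a cylindrical gel dosimeter and multi-sphere LRT
    dose distributions so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
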