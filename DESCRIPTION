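Package: tumorPAS
Title: Free-Boundary Tumor Growth Model of the Plasminogen Activation System
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Radially symmetric free-boundary reaction-diffusion-advection
    model of recurrent breast-tumor growth coupled to the plasminogen
    activation system (uPA, uPAR, PAI-1) and its tumor microenvironment
    (macrophages, endothelial cells, fibroblasts, ECM, oxygen, VEGF, MMP/TIMP).
    Provides a reproducible parameter-derivation layer, a moving-mesh
    finite-difference solver (explicit total-derivative scheme and an
    operator-split implicit-diffusion scheme with a compiled core), the
    total-uPAR/tumor-radius biomarker surfaces and their inversion, and
    Latin hypercube + partial rank correlation sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
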