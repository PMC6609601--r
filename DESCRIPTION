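Package: pedpanodose
Title: Effective Dose Estimation and Dose-Factor Sensitivity Analysis for
    Paediatric Panoramic Radiography
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for radiation dosimetry of paediatric dental panoramic
    radiography. Implements the thermoluminescent dosimeter (TLD)
    measurement-processing chain (chip screening, background subtraction,
    gamma-energy correction, site averaging) through to an ICRP-103
    effective dose using packaged fraction-irradiated and tissue-weighting
    tables for the head and neck of a 5-year-old; a voxelized Monte Carlo
    photon-transport simulator with a rotational narrow-beam source
    geometry, Kramers-law filtered spectra and dose-area-product
    normalization; and a one-factor-at-a-time sensitivity analysis that
    ranks the machine and exposure factors determining the effective dose
    by simple linear regression.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml,
    jsonlite,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
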