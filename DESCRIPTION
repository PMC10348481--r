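Package: osteosect
Title: Quantitative Analysis of Transiliac Bone Sections
Version: 0.1.0
Authors@R:
    person("Osteosect", "Developers", email = "osteosect@example.org",
           role = c("aut", "cre"))
Description: Calibrated analysis of transiliac bone biopsy cross-sections:
    two-point (carbon/aluminum) calibration of quantitative backscattered
    electron images to calcium weight percent, bone mineralization density
    distribution (BMDD) histograms and their canonical parameters (CaMean,
    CaPeak, CaWidth, CaLow, CaHigh) per compartment, two-dimensional
    structural and static histomorphometry (BV/TV, Tb.Th, Tb.N, Ct.Wd,
    osteoid and cell-surface indices), and bone-marrow adipocyte area
    quantification.  A seeded synthetic-section generator produces paired
    images, phase label maps and ground truth so the whole pipeline is
    testable without specimen data.  Includes pediatric reference ranges,
    z-score comparison, a report builder and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
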