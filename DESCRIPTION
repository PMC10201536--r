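Package: tautopath
Title: Proton-Transfer Energy Landscapes and Steered Unzipping of DNA Base Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale pipeline for studying adenine-thymine double-proton-transfer
    tautomerization during DNA strand separation. Provides a calibrated
    two-coordinate model energy surface parameterized by strand-separation
    distance, a constrained separation-scan protocol, nudged-elastic-band
    minimum-energy-path search with an optional Gaussian-process surrogate,
    barrier/asymmetry/stability analytics with onset detection and power-law
    fits, and constant-force steered Langevin unzipping of a coarse-grained
    duplex with opening-angle and separation-speed statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    Matrix,
    yaml,
    generics,
    digest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
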