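Package: lpbarcode
Title: Combinatorial Laser-Particle Barcoding of Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Planning, simulation and analysis tools for combinatorial
    optical barcoding of single cells with laser particles (LPs). Provides
    closed-form and Monte-Carlo models of barcode duplication and
    noise-induced misidentification, matching-threshold optimization and
    pool-size planning, seeded simulators of barcode pools (including
    Poisson tagging multiplicity, dual-mode LPs and multiplet inheritance
    across cell divisions), spectral barcode extraction (peak detection,
    Gaussian line fitting, spatial-spectral clustering), and a cross-run
    barcode matching algorithm with score-threshold selection and
    generalized-Gaussian noise-model estimation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
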