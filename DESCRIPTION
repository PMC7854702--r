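Package: phytosaxs
Title: Small-Angle Scattering Shape and Dynamics Analysis for Phytochrome Photostates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for solution small-angle X-ray scattering (SAXS)
    studies of dimeric plant photoreceptors. Decomposes photosteady-state
    scattering of a red-light-irradiated phytochrome solution into pure Pr and
    Pfr profiles using populations estimated from absorption spectra, performs
    Guinier and dilution-series analysis (molecular weight, second virial
    coefficient, infinite-dilution radius of gyration), simulates scattering
    from dummy-residue bead models via the Debye formula, classifies large
    ab initio bead-model ensembles into representative molecular shapes by
    voxel densities, principal component analysis and k-means clustering,
    runs anisotropic elastic-network normal-mode analysis of C-alpha
    structures with B-factor based cutoff calibration, and computes
    Smith-Waterman local alignments with EMBOSS Water conventions. A
    synthetic-data module generates every input at desk scale with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    stats,
    utils,
    generics,
    ggplot2,
    bio3d,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
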