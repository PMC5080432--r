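Package: aucbind
Title: Nanoparticle-Protein Binding Analysis by Sedimentation-Velocity
    Analytical Ultracentrifugation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing nanoparticle-protein interactions from
    sedimentation-velocity analytical ultracentrifugation (SV-AUC). Implements
    the closed-form hydrodynamic relations linking sedimentation and diffusion
    coefficients to hydrodynamic size, density and frictional ratio; a
    conservative finite-volume Lamm-equation simulator for sector-shaped cells;
    a regularized sedimentation-coefficient distribution inversion; Hill
    adsorption-isotherm fitting of mean sedimentation coefficients versus
    protein concentration to estimate the dissociation constant, maximum
    stoichiometry and Hill coefficient; and frictional-ratio shape-evolution
    analysis of nanoparticle-protein complexes. Includes a synthetic-data
    generator emulating triplicate binding isotherms and noisy radial scan
    sets so the full pipeline can be exercised without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    pracma,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
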