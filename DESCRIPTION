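Package: npwrap
Title: Elastic Wrapping Theory and Dosimetry for Nanoparticle-Liposome
    Interactions
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative toolkit for size-dependent interactions between
    gold nanoparticles and large unilamellar lipid vesicles. Implements
    elastic membrane-wrapping theory (critical diameters with and without
    membrane tension, curvature-corrected contact energies, adhesion
    critical diameters), an isoperimetric tension-lockout model for the
    number of nanoparticles a vesicle can fully engulf, liposome and
    nanoparticle dosimetry (lipids per vesicle, number concentrations,
    surface-area ratios, calcein-based vesicle counting), reduction of
    isothermal titration calorimetry thermograms to surface-area-normalised
    enthalpies, fluorescence assay reductions (calcein leakage, Nile Red
    emission-peak shifts), a forward dynamic light scattering mixture model
    with cumulant analysis, and seeded synthetic-data generators with
    ground truth for every instrument readout the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
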