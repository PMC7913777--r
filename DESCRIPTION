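Package: sedlink
Title: Sedimentation and Calorimetric Analysis of Linked Protein Assembly Equilibria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Thermodynamic and hydrodynamic analysis of reversible protein
    self-association and ligand linkage, built around the E. coli RecR
    dimer-tetramer system and its RecO/SSB-Ct partners. Provides
    sedimentation-equilibrium forward models and global nonlinear
    least-squares fitting (multi-speed, multi-loading, with optional mass
    conservation), Wyman linkage analysis of pH-dependent association
    constants with proton-uptake slopes, a reaction-coupled finite-volume
    Lamm-equation simulator for sedimentation velocity of interacting
    systems, a regularized sedimentation-coefficient distribution
    (c(s)-style) analyzer with a transport-method cross-check, isothermal
    titration calorimetry forward models and fitting for n identical
    independent sites, and seeded synthetic-data generators that emulate
    the corresponding experimental designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    Matrix,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    parallel
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
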