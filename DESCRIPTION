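Package: ssipr
Title: Surface Site Interaction Points and Liquid-Phase Equilibria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grains a molecular electrostatic potential surface into
    discrete Surface Site Interaction Points (SSIPs) and solves the SSIMPLE
    pairwise-equilibrium model for liquid phases. Reads Gaussian cube grids,
    XYZ and minimal CML structures, SSIP XML descriptors and tab-separated
    phase definitions; extracts the 0.002 e/bohr^3 electron-density
    isosurface, footprints it into equal-area signed interaction sites,
    computes speciation of free and bound sites in solvent mixtures, and
    derives solvation and phase-transfer free energies, functional group
    interaction profiles (FGIPs) and solvent similarity indices (SSIs).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    xml2,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
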