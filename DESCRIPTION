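Package: poremcm
Title: Monte Carlo Minimization Modelling of Ligand Block in P-Loop Channel Pores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale Monte Carlo energy minimization (MCM) toolkit for
    modelling cationic blocker binding in the pore domain of P-loop channels
    such as the cardiac sodium channel Nav1.5.  Provides the universal
    k/o/p/i residue labelling scheme with packaged hNav1.5 anchors, structure
    reading/writing and P1-helix superposition, a reduced nonbonded energy
    model with cutoff shifting and distance-dependent dielectric, flat-bottom
    pin / plane / axial-distance restraints, an MCM engine with pose-stack
    clustering, random-start ligand docking, in-silico voltage-sensor
    deactivation by plane-constrained S4 pulling, ligand egress energy
    profiling through inter-repeat fenestrations, fenestration geometry and
    lipid-interface residue census analyses, and a synthetic toy-channel
    generator so every protocol is testable without external structures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
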