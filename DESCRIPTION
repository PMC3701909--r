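Package: smkin
Title: Single-Molecule pMHC:TCR Binding Kinetics and Simulation Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of single-molecule imaging experiments
    that measure peptide-MHC binding kinetics at the T cell receptor (TCR).
    Provides a synthetic-data generator for two-dimensional Brownian tracks
    in a supported lipid bilayer, two-state (free/bound) trajectories with
    photobleaching, stepwise fluorophore intensity traces, rendered camera
    frame stacks and fiducial bead fields; spot detection and track linking;
    Rayleigh mixture analysis of step-size distributions; Bayesian
    change-point detection of intensity steps; photobleach-corrected
    dwell-time estimation of the molecular off time; two-channel fiducial
    registration; fluorophore-counting stoichiometry of ZAP70 recruitment;
    and an event-driven stochastic lattice simulation of ligand escape from
    receptor clusters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tiff,
    withr
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
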