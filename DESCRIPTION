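Package: ramfes
Title: Replica-Averaged Metadynamics, Free-Energy Reconstruction and
    NMR Ensemble Validation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying multi-state conformational free-energy
    landscapes of proteins with bias-exchange metadynamics under
    replica-averaged chemical-shift restraints. Provides PDB structure and
    ensemble handling with geometric primitives (backbone and side-chain
    dihedrals, group centroids, inter-group angles), the dihedral-correlation
    and helix-orientation collective variables, a seeded Langevin/metadynamics
    engine for analytic toy potentials, WHAM free-energy reconstruction over
    collective-variable microstates with basin detection and Boltzmann state
    populations, SVD fitting of residual dipolar coupling alignment tensors
    with Q-factor ensemble validation, and secondary-structure population
    analysis. Includes seeded generators for calibrated multi-basin
    potentials, ideal peptides, labelled multi-state ensembles and synthetic
    NMR observables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
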