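Package: lvmetad
Title: Localized-Volume Well-Tempered Metadynamics for Ligand Binding on
    Model Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale simulator and analysis toolkit for localized-volume
    well-tempered metadynamics (LV-MetaD) studies of ligand binding on shallow
    protein-surface pockets.  Provides underdamped Langevin dynamics on model
    host-guest potentials with brute-force free-energy oracles, the
    parabolic-solid collective variables (rho, tau, theta) with restraining
    walls, well-tempered Gaussian hill deposition, Tiwary-Parrinello
    reweighting, free-energy projection onto a distance / hydrogen-bond-count
    map with block-average errors, watershed basin detection, and
    standard-state binding free energies.  Reads and writes PLUMED-style
    COLVAR, HILLS and FES text files so externally produced trajectories can
    be analysed with the same tools.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
RoxygenNote: 7.3.3
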