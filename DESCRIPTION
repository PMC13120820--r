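Package: kvperm
Title: Ion Permeation and Pore-Blocker Analysis for Kv Channel Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis toolkit for studying potassium permeation and
    small-molecule block in voltage-gated K+ (Kv) channel simulations.
    Provides pore-frame geometry (axis and cylindrical projection of ion
    and ligand trajectories), selectivity-filter site mapping and
    occupancy assignment, single-file permeation-event detection with
    single-channel conductance estimation, axial ion density profiles,
    ligand-protein contact statistics under a distance-cutoff rule,
    planar and volumetric occupancy maps (OpenDX export), evaluation of
    dihedral-bias, flat-bottom and knock-on restraint potentials with
    analytic gradients, constant-field voltage mapping, and a seeded
    continuous-time Markov chain simulator of the knock-on conduction
    cycle that generates synthetic ion and ligand traces with exact
    ground truth for validating every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
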