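Package: azsim
Title: Voxel-Based Simulation of Calcium Microdomains at Presynaptic
    Active Zones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Spatially resolved simulation of calcium microdomains at the
    Drosophila neuromuscular-junction active zone. Builds voxelized 3D
    geometries of the active zone with or without the T-bar diffusion
    obstacle, models voltage-gated calcium influx (Goldman-Hodgkin-Katz
    flux with Borg-Graham style gating), PMCA/NCX extrusion pumps, a
    calibrated leak, and mobile-buffer kinetics, and advances the coupled
    two-species diffusion-reaction system on a Cartesian voxel grid with
    an operator-split implicit solver. Circle-probe evaluation quantifies
    the near-membrane and under-roof calcium enhancement produced by the
    T-bar and by channel clustering, including grid-convergence
    diagnostics and parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    graphics,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
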