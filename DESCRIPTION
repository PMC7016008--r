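Package: atrialwave
Title: Personalized Atrial Fibrillation Simulation on Triangular Surface Meshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monodomain simulation of atrial fibrillation on triangular
    surface meshes with the Courtemanche-Ramirez-Nattel human atrial
    myocyte model and AF/fibrosis ionic remodeling. Builds personalized
    models from electro-anatomical maps: inverse-distance-weighted
    interpolation of bipolar voltage and activation time, probabilistic
    voltage-to-fibrosis assignment, fiber-anisotropic conduction tuned to
    clinical conduction velocities, ramp-pacing AF induction, dominant
    frequency and phase-singularity wave-dynamics analysis, and forward
    bipolar electrogram reconstruction. Includes a deterministic
    synthetic-data factory (meshes, fiber fields, electro-anatomical maps,
    plane-wave and spiral-wave movies) so the whole pipeline is exercisable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Matrix,
    methods,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
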