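Package: dlcm
Title: Discrete Laplacian Cell Mechanics for Simulating Cell Populations
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An event-driven, continuous-time simulator for populations of
    biological cells living on voxel tessellations (Cartesian 2D/3D, hexagonal,
    or unstructured Voronoi grids). Voxels hold at most two cells; overcrowded
    voxels act as unit sources for a cellular pressure field governed by a
    discrete Laplace equation, and pressure gradients across voxel edges are
    converted into stochastic movement rates sampled exactly with the Gillespie
    direct method. The mechanics couple to chemotactic drift fields, per-cell
    signalling ODEs (Delta-Notch lateral inhibition), and oxygen-driven
    avascular tumour kinetics with proliferating, quiescent and necrotic
    compartments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    deSolve,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
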