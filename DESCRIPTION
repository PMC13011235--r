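Package: poreflow
Title: Pore-Scale Lattice Boltzmann Permeability and Structural Analysis
    of Cellular Solids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Central-moment lattice Boltzmann solver (D2Q9/D3Q27) for the
    intrinsic Darcy permeability of binary pore-space images, validated
    against plane Poiseuille flow, the Gebart hexagonal cylinder array and
    the face-centred-cubic sphere packing.  Includes a seeded synthetic
    foam generator emulating bread-crumb microstructure, image-derived
    structural descriptors (porosity, effective porosity, connectivity,
    local-thickness pore-size distribution, skeleton tortuosity, junction
    counts), voxel coarsening and representative-elementary-volume tools,
    and Spearman descriptor-permeability correlation workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    tibble,
    generics,
    ggplot2,
    rlang,
    tiff,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
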