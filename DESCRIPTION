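Package: nucleodrop
Title: Nuclear Drop Model Shape Solver and Endothelial Monolayer Morphometrics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes equilibrium cell and nuclear shapes under the nuclear
    drop model: the cell cortex is a minimal-area surface over a fixed
    adhesion footprint, and the nucleus is a pressurized drop with an
    inextensible lamina, so its shape is set purely by geometric constraints
    of constant volume and constant surface area. Shapes are obtained by
    penalty-constrained energy minimization over triangulated surfaces kept
    near a centroidal Voronoi tessellation, with a reflecting-boundary
    treatment of cortex/nucleus/substrate/micropost contact and quasi-static
    micropost indentation. A companion image-analysis toolkit quantifies
    nuclear wrinkling by elliptical Fourier analysis (EFC ratio), nuclear
    height, surface area and volume from confocal z-stacks, monolayer
    height maps and roughness, YAP nuclear-to-cytoplasmic ratios, focal
    adhesion density, and pMLC intensity, together with seeded permutation
    tests and synthetic-data generators with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    pracma,
    yaml,
    jsonlite,
    tiff,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
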