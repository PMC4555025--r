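Package: vesicle3d
Title: Shape, Orientation and Spatial Interaction Analysis of Synaptic
    Vesicles in 3D
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Morphometry and spatial statistics for synaptic vesicles
    reconstructed from isotropic volume electron microscopy (FIB-SEM)
    label stacks. Fits ellipsoids to annotated vesicle boundaries,
    computes size, shape (elongation, fractional anisotropy, mode of
    anisotropy) and orientation statistics relative to the active zone,
    vesicle density profiles with quasi-Poisson regression, and
    un-edge-corrected K- and L-functions and mark variograms for marked
    point patterns of vesicle centers. Spatial interaction beyond
    physical extent is tested against a hard-core null model (vesicles
    placed uniformly at random subject to non-overlap inside the
    irregular synapse domain) simulated by a Metropolis relocation
    chain, with pointwise simulation envelopes. A synthetic data
    generator produces domains, vesicle configurations with known
    interaction structure, and voxelized label stacks for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tiff
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
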