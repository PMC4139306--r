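Package: memesp
Title: Electrostatic Potentials of Lipid Membranes: Grids, Robust Averaging and Similarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for computing, averaging and comparing three-dimensional
    electrostatic potential grids of lipid bilayer systems containing charged
    phosphoinositide headgroups. Reads and writes UHBD (binary and ASCII) and
    OpenDX volumetric grids; solves the linearized finite-difference
    Poisson-Boltzmann equation with two-level focusing; averages grid
    ensembles voxel-wise by arithmetic mean, exact median, or the streaming
    remedian; compares potentials over solvent skin regions with the Hodgkin
    similarity index and the derived electrostatic distance; measures the
    height of the isopotential bulge above the phosphoinositide phosphate and
    the headgroup tilt geometry. A synthetic bilayer generator with an
    analytic screened-Coulomb potential provides desk-scale ensembles so the
    whole pipeline can be exercised and validated without molecular dynamics
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
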