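Package: glycofel
Title: Ring-Puckering Coordinates, Metadynamics Free-Energy Reconstruction
    and Catalytic-Geometry Analysis for Glycosidase Mechanisms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cremer-Pople puckering coordinates for six-membered (pyranose)
    rings with canonical conformer classification on the full 38-conformer
    sphere; normalized puckering collective variables and a signed
    multi-distance reaction coordinate for glycoside hydrolysis; a
    standard (fixed-height-schedule) metadynamics engine with PLUMED-style
    HILLS/COLVAR text input and output, free-energy-landscape
    reconstruction and an overdamped-Langevin toy sampler for validating
    the full bias-deposition loop; recrossing-cycle segmentation of biased
    reaction trajectories with Boltzmann (exponential) profile averaging,
    standard-deviation and standard-error bands, and barrier extraction;
    per-frame catalytic-geometry analysis including low-barrier
    hydrogen-bond detection, oxocarbenium-character descriptors and
    conformational-itinerary strings; and seeded synthetic-trajectory
    generators for every analysis input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
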