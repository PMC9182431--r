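Package: sopmech
Title: Coarse-Grained SOP-Model Mechanics of AAA+ Unfoldase Action
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds interface-resolved Go-like (self-organized polymer, SOP)
    topologies from C-alpha structures, runs overdamped Brownian-dynamics
    force spectroscopy (constant-loading-rate cantilever pulling and a
    ClpY-style repetitive pore-force translocation protocol), and computes
    the standard observables of AAA+ unfoldase studies: fractions of native
    and non-native contacts, first and critical breaking forces, fragment
    and oligomer censuses with severing-pathway labels, machine-substrate
    orientation angles, free-energy landscapes, and translocation metrics.
    Includes deterministic generators for desk-scale synthetic systems
    (microtubule-like lattices, hexameric ring machines with pore loops and
    MIT-like arms, anisotropic beta-sheet globules with pulling tails).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    igraph,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
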