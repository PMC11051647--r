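Package: glossim
Title: Spatial Age-Structured Simulation of Riverine Tsetse Control by
    Tiny Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A deterministic, spatially explicit, daily age-structured
    simulator of riverine tsetse (Glossina fuscipes fuscipes) population
    dynamics on a 1-km lattice of habitat classes, and of their suppression
    by insecticide-treated Tiny Targets. Implements density-dependent
    natural mortality, larviposition and pupal development, calibrated
    orthogonal diffusion with habitat-dependent damping, age- and
    sex-dependent target kill schedules with first-order degradation and
    six-monthly refreshment, a schematic river-network landscape generator,
    a phased deployment scenario runner, and the derived control metrics
    (percent of the pre-control population remaining, age-structure
    fractions, pupal production, along-river transects).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    methods,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
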