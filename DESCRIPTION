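Package: tmdimer
Title: Interface Analysis of Transmembrane Helix Dimers in Coarse-Grained
    Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize the dimerization interfaces of
    single-pass transmembrane helices in coarse-grained (MARTINI-style)
    simulation output: residue-residue contact maps and an NMR-similarity
    score, Dice/UPGMA clustering of interfaces, dimer geometry (helix
    axes, signed crossing angles, tilt, helix-length distributions),
    interface kinetics (retention times and pruned transition networks),
    sampling-completeness statistics with double-exponential fits of
    subsampled Pearson correlation curves, and elastic-network style
    augmentation of coarse-grained helix topologies.  A synthetic-data
    module generates two-helix trajectories with planted interface states
    and Markov switching so every analysis stage can be validated without
    running molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    graphics,
    igraph,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
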