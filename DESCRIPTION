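Package: gridscape
Title: Grid-Cell Responses to Environmental Geometry in an Oscillatory
    Network Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a hierarchical oscillatory model of entorhinal grid
    cells -- a self-organizing head-direction layer, a forced limit-cycle
    oscillator layer performing path integration, and a lateral
    anti-Hebbian network (LAHN) extracting principal-subspace features --
    inside two-dimensional arenas of configurable geometry (regular
    polygons, connected rooms, annulus/horseshoe/S concave shapes, and a
    rectangle that transforms into a square during exploration).  Provides
    curvature-constrained random foraging trajectories, firing-rate maps,
    spatial autocorrelograms, hexagonal gridness scores (including
    local/global scores for compartmentalised arenas, ellipticity and
    half-arena similarity), trend analyses over arena parameters, and a
    multilayer-perceptron decoder that reads the arena configuration out
    of the LAHN population activity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    nnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
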