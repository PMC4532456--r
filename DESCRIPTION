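Package: graphdyn
Title: Graph Dynamical Systems: Phase Spaces, Attractors and Stability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Build and analyze discrete graph dynamical systems (GDS):
    finite-state automata networks over dependency graphs evaluated under
    synchronous, sequential, block-sequential or unfair word update schemes.
    Supports threshold, bithreshold, nor, multi-state multi-threshold and
    weighted linear-threshold vertex functions, full phase-space enumeration
    with limit cycles, transients and basins of attraction, functional and
    cycle equivalence between systems, attractor graphs under single-vertex
    perturbations with their ergodic sets (strongly connected components),
    fixed-point condition checking for three-state threshold systems, and
    factorized fixed-point counting over independent components.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    tibble,
    tidyr,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
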