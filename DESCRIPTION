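Package: cyanoswarm
Title: Self-Propelled Particle Simulation and Analytics for Gliding
    Cyanobacterial Collective Motion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates collective gliding of filamentous cyanobacteria with a
    Vicsek-class self-propelled particle model combining nematic alignment,
    Ornstein-Uhlenbeck persistence of individual rotation rates, and
    short-range attraction/repulsion on an unbounded plane.  Provides the
    analytics used to characterise the emergent scattered colony patterns:
    single-linkage cluster detection and tracking, wandering/rotating
    trajectory classification, passing-count occupancy maps, kymographs,
    radial speed profiles, collision-angle statistics, window
    cross-correlation particle image velocimetry, and heavy-tail inference
    for cluster-size distributions (Clauset-style power-law and truncated
    log-normal fits with KS-minimising lower cut-off, semiparametric
    bootstrap goodness-of-fit, and Vuong model selection).
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    igraph,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
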