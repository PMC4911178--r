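Package: syncytia
Title: Stochastic Spatial Modelling of Nuclear Clustering in the
    Syncytiotrophoblast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the aggregation of nuclei in the human placental
    syncytiotrophoblast as interacting Brownian particles with a short-range
    adhesive contact potential, confined to a corrugated two-dimensional strip
    whose upper boundary is an interpolated Ornstein-Uhlenbeck profile.
    Provides connected-component cluster censuses (Tarjan-style), replicated
    parameter sweeps over adhesion, diffusion, fusion-site spread and boundary
    amplitude, morphometric quantification rules for syncytial nuclear
    aggregates and clusters on micron-unit point patterns (nearest-neighbour
    edge-to-edge distances, size and density metrics, particle-size censuses),
    and ground-truthed synthetic pattern generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    graphics,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
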