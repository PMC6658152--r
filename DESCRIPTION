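Package: fundusgraph
Title: Network and Fractal Characterization of Retinal Fundus Vasculature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts weighted tree-like graphs from segmented retinal fundus
    vasculature and characterizes them with central node-distance, central
    mean-weight and weighted-degree distributions, box-counting fractal
    dimensions of raw and skeletonized vessel masks, pairwise Jensen-Shannon
    divergences between per-image distributions, IsoMap embedding of the
    divergence matrix, and two-sample group tests. Includes a ground-truthed
    synthetic fundus generator (branching vascular trees with optic disc and
    width tapering), a diffusion-limited-aggregation simulator and analytic
    fractal phantoms, so the whole pipeline is testable without external
    image databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    yaml
Config/testthat/edition: 3
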