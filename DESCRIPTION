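Package: routenet
Title: Network Extraction from Routing Optimization Solutions and Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts explicit weighted spatial networks from solutions of
    continuous routing-optimization problems and from raster images. Provides
    a finite-element solver for the dynamical Monge-Kantorovich (Physarum-type)
    equations on triangulations of the unit square, rule-based graph
    pre-extraction from thresholded conductivity fields, a principled graph
    filter driven by the discrete Monge-Kantorovich / basis-pursuit dynamics
    with terminal selection by convex hull and betweenness centrality, and
    evaluation metrics including a partition-based local-weight discrepancy,
    total network length, and vein-length distribution analysis with
    exponential fits.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Matrix,
    minpack.lm,
    jsonlite,
    yaml,
    png,
    tiff,
    grDevices,
    graphics,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
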