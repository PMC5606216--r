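Package: subcellnet
Title: Constrained Force-Directed Layout of Biomolecular Networks in a Cell Diagram
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Headless layout engine and renderer for biomolecular interaction
    networks annotated with subcellular localization. Reads XGMML networks
    whose nodes carry a single-valued compartment attribute ("Selected CC" or
    "Localization"), builds a circle-only cell diagram (concentric cell wall,
    plasma membrane, cytoplasm and nucleus plus free-floating organelle
    discs), and runs a force-directed simulation in which every node is
    projected back into its annotated compartment after each iteration.
    Includes quad-tree accelerated many-body forces and collision resolution,
    force-directed edge bundling, topology metrics (degree, betweenness,
    clustering coefficient), per-compartment counts, and deterministic
    SVG/PNG/CSV export.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    xml2,
    jsonlite,
    optparse,
    grDevices,
    graphics,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
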