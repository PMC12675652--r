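Package: asymweb
Title: Asymmetry Graphs and Topological Importance Indices for Food Webs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes pairwise n-step topological importance (TI^n) effects
    from binary, undirected food-web topology, extracts the most asymmetric
    effect pairs into a directed, weighted asymmetry graph, and derives a
    suite of 21 systemic indicators (food-web structure, asymmetry-graph
    structure, and non-network ecosystem measures) together with a pairwise
    Kendall correlation screen under Benjamini-Hochberg false-discovery-rate
    control. Includes readers for edge lists and Ecopath-style diet matrices,
    prey-averaged trophic-level computation, and a seeded niche-model
    generator of synthetic food webs with biomass and ecotrophic-efficiency
    attributes for offline testing of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
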