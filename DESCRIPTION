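Package: pollinet
Title: Site-Pollinator Bipartite Network Analysis and Pollination Function
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing weighted bipartite networks that link field
    sites (habitats) to the flower-visitor species recorded at them. Computes
    node-level specialization (d'), species strength, Barber weighted
    modularity maximized by simulated annealing, vaznull-style null models
    with null-derived critical thresholds, and Guimera-Amaral node roles
    (participation coefficient and within-module degree). Links network
    position to sentinel-plant reproduction through variance-weighted
    quasi-likelihood GLMs, land-use comparisons, pairwise distance
    regressions and AICc model selection, and ships a synthetic landscape
    generator with planted modules and known effect sizes for end-to-end
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    geosphere,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
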