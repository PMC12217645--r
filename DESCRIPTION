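Package: shelfprov
Title: Distance-Based Bioregionalisation of Gridded Occurrence Data with a
    Cluster Coherence Index
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for biogeographic regionalisation of shallow-water
    occurrence records on an equal-area grid. Implements Darwin-Core-style
    record cleaning, Behrmann equal-area gridding, per-rank incidence
    matrices, Simpson (turnover) dissimilarities, UPGMA/WPGMA clustering
    with cophenetic validation and an objective dendrogram cut-off-selection
    rule, a Cluster Coherence Index that scores the geographic coherence of
    clusters, non-metric multidimensional scaling with sea-surface
    temperature surface fits (generalised additive models) and permutation
    Mantel tests, and a seeded synthetic-world generator with planted
    provinces for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    geosphere,
    vegan,
    mgcv,
    ape,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
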