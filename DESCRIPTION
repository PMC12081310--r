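Package: atlasq
Title: Query Assessment Against Single-Cell Reference Atlases
Version: 0.1.0
Authors@R: person("Atlas", "Maintainers", email = "maintainers@atlasq.dev", role = c("aut", "cre"))
Description: Tools to project single-cell organoid query datasets onto a
    reference atlas, transfer hierarchical cell-type labels by k-nearest
    neighbours, quantify on- and off-target identity, reconstruct a matched
    atlas reference per query cell, test differential expression with a
    paired F statistic, score organoid fidelity by neighbourhood
    correlation, detect disease-associated cell states by distance to the
    atlas, attribute pseudo-bulk variance to sample covariates, and score
    drug-target signatures. Includes a seeded synthetic multi-tissue atlas
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    data.table,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
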