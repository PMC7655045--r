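Package: commgeom
Title: Communicability Geometry and Shortest Communicability Paths on Binary Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Communicability-distance geometry on binary undirected networks:
    the communicability matrix exp(zeta*A) and subgraph centralities, the
    Euclidean communicability distance between nodes, shortest communicability
    paths on the communicability-weighted adjacency and their edge-averaged
    normalization, the susceptible-infected (SI) propagation model together
    with its linearized and bounded surrogate solutions, edge-removal
    diagnostics separating circulability from transmissibility, and a
    two-group connectome comparison pipeline (binarization, group-mask
    thresholding, permutation tests with FDR and Bonferroni correction, pair
    classification and node profiles) with a synthetic cohort generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
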