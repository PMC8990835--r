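Package: netattack
Title: Drug-Attack Robustness Scoring of Disease Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the effect of multi-target drugs on disease
    protein-protein interaction networks by simulated node-deletion
    attacks. Builds disease networks and per-pathological-process
    functional subnetworks from gene-disease association and PPI
    tables, measures robustness change with four whole-graph topology
    statistics (average degree, average shortest path length, degree
    centralization, closeness centralization), normalizes each
    robustness index against a fixed-edge-count random-network
    permutation null, and combines the z-scores into a composite
    attack score used to rank agents. Includes a synthetic-data
    generator with planted functional modules for end-to-end
    validation, and peak-area-ratio aggregation for ranking
    compound-targeted pathological processes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
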