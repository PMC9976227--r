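Package: supplynet
Title: Trade-Network Characterization and External Supply-Risk Scoring
Version: 0.1.0
Authors@R:
    person("supplynet", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Builds directed bilateral trade networks from long-format flow
    tables, binarizes them at a configurable USD threshold, and computes
    network density, degree statistics, trade-share concentration tables and
    exponential degree-distribution fits. Detects trade communities with an
    in-package Louvain modularity optimizer and counts absolute-dependence
    supplier pairs. Scores each importing country's external supply risk from
    three components - external dependence (imports over GDP), import
    concentration (Herfindahl-Hirschman) and epidemic exposure
    (import-share-weighted supplier risk index) - sums them into a composite,
    grades all indices by Fisher-Jenks natural breaks or equal intervals, and
    labels the dominant risk type. Includes a gravity-model synthetic-world
    generator so the whole pipeline is testable without external data, and a
    command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
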