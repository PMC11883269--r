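Package: mpclineage
Title: Stochastic Lineage Competition and Quantitative Lineage Analysis
    for De Novo Meristem Formation in Fern Gametophytes
Version: 0.1.0
Authors@R:
    person("Riley", "Calder", email = "riley.calder@posteo.net",
           role = c("aut", "cre"))
Description: Simulates and analyses the emergence of a single dominant cell
    lineage (the meristem progenitor cell, MPC) during male-to-hermaphrodite
    conversion in Ceratopteris gametophytes. Provides a stochastic
    differential-equation model of five competing lineages with Hill-type
    lateral inhibition (threshold and mutual-inhibition variants) integrated
    by Euler-Maruyama, ensemble post-processing with rank-sorted mean and
    standard-deviation curves, quantitative analytics for cell-lineage
    tracking tables (per-lineage cell counts, windowed division maps,
    layer-specific progeny division totals, division-orientation frequencies,
    Welch's t comparison), a watershed-based nuclei segmentation pipeline
    with programmatic label curation, and seeded synthetic-data generators
    that emit lineage tables and nuclei image series together with
    ground-truth ledgers for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
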