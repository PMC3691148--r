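Package: siglinc
Title: Signed Link Clustering for Molecular Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of signed undirected molecular networks such as gene
    coexpression networks and genetic interaction networks. Computes per-edge
    signed link-clustering coefficients (LC and its same-sign, hybrid, positive
    and negative subtypes), a signed triad census with a sign-shuffling null
    model and empirical enrichment statistics, common-neighbor profile
    correlations for negative links, and link-community module discovery on
    positive links with a partition-density-maximising score cutoff. Includes
    builders for Pearson-correlation-thresholded coexpression networks and for
    sign-mapped genetic-interaction networks from BioGRID-style tables, plus
    synthetic generators (balanced block networks, signed Erdos-Renyi graphs,
    planted-module expression matrices) with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
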