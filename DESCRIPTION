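Package: orcci
Title: Ollivier-Ricci Curvature Community Detection with Side Information
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Community detection for undirected biological networks based on
    Ollivier-Ricci edge curvature: iterative removal of the most negatively
    curved edge with exact Wasserstein-1 transport, optional protection of
    edges whose endpoints share a-priori functional labels (side
    information), stochastic block model benchmarks with partial
    observability and corrupted labels, and evaluation metrics (normalized
    mutual information, pairwise information-retrieval scores, pathway
    protein ratio, community overlap reports).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
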