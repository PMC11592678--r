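Package: critedge
Title: Critical Edge Identification in Undirected Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies critical edges in undirected simple networks with a
    global-local hybrid centrality that combines pair-normalized edge
    betweenness with first- and second-order neighborhood overlap indices.
    Implements seven comparison indices (degree product, edge betweenness,
    bridgeness, diffusion intensity, a motif-based edge importance metric,
    and the first/second-order neighborhood Jaccard indices), an edge
    percolation framework measuring robustness, connectivity degradation and
    ranking monotonicity, and seeded Erdos-Renyi, Barabasi-Albert and
    Watts-Strogatz generators for benchmarking without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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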