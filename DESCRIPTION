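Package: snefldsm
Title: Key Node Identification in Complex Networks via an Entropy-Fused
    Spring Model with Fuzzy Local Dimension
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies influential spreaders in undirected, unweighted
    networks with the SNEFLD-SM method: second-order neighborhood
    betweenness entropy (an information-entropy fusion of betweenness and
    two-hop degree mass), a fuzzy local fractal dimension computed by
    Gaussian-membership box covering, a spring-model aggregation of
    pairwise influence forces with a per-node influence range, and a
    greedy ranking with neighbor attenuation that suppresses rich-club
    redundancy among top spreaders. Includes the full evaluation harness:
    stochastic susceptible-infected (SI) spreading, the mean-field SI
    logistic reference, per-node infectivity, Kendall tau rank
    correlation, top-k Jaccard overlap, and robustness curves under
    targeted node removal, together with seeded Erdos-Renyi and canonical
    fixture generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
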