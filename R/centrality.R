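#' Degree centrality
#'
#' Raw degree \eqn{DC(i) = \sum_j a_{ij}}: the number of direct neighbors.
#' Not normalized, so \eqn{\sum_i DC(i) = 2E}.
#'
#' @param g a connected igraph graph.
#' @return named numeric vector of scores (a score map), names = node labels.
#' @export
degree_centrality <- function(g) {
  g <- as_simple_named(g)
  s <- igraph::degree(g, loops = FALSE)
  stats::setNames(as.numeric(s), V(g)$name)
}

#' Second-order neighborhood centrality
#'
#' \eqn{CSN(i) = \sum_{u \in \Gamma(i)} DC(u)}: the total degree mass of a
#' node's neighbors, capturing two-hop local influence. On an r-regular graph
#' every node scores r^2.
#'
#' @inheritParams degree_centrality
#' @return named numeric score map.
#' @export
second_order_centrality <- function(g) {
  g <- as_simple_named(g)
  dc <- degree_centrality(g)
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  stats::setNames(as.numeric(A %*% dc), V(g)$name)
}

#' Betweenness centrality
#'
#' \eqn{BC(i) = \sum_{\{j,k\}, j \ne i \ne k} N_{jk}(i) / N_{jk}} over
#' unordered pairs, where \eqn{N_{jk}} counts geodesics between j and k and
#' \eqn{N_{jk}(i)} those passing through i. Raw (unnormalized), endpoints
#' excluded; computed with Brandes' algorithm.
#'
#' @inheritParams degree_centrality
#' @return named numeric score map.
#' @export
betweenness_centrality <- function(g) {
  g <- as_simple_named(g)
  s <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  stats::setNames(as.numeric(s), V(g)$name)
}

#' Closeness centrality
#'
#' Standard closeness \eqn{CC(i) = (n-1) / \sum_j d_{ij}}, included as a
#' comparator for ranking studies.
#'
#' @inheritParams degree_centrality
#' @param dm optional precomputed [all_pairs_distances()] matrix.
#' @return named numeric score map.
#' @export
closeness_centrality <- function(g, dm = NULL) {
  g <- as_simple_named(g)
  if (is.null(dm)) dm <- all_pairs_distances(g)
  n <- gorder(g)
  stats::setNames((n - 1) / rowSums(dm), V(g)$name)
}

#' Local entropy
#'
#' \eqn{LE(i) = -\sum_{j \in \Gamma(i)} DC(j)\,\log DC(j)} with natural logs
#' and raw degrees. Degree-1 neighbors contribute 0 (1 log 1). Note the
#' degrees enter as printed in the defining formula, not renormalized to
#' probabilities; see the methods vignette.
#'
#' @inheritParams degree_centrality
#' @return named numeric score map.
#' @export
local_entropy <- function(g) {
  g <- as_simple_named(g)
  dc <- degree_centrality(g)
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  stats::setNames(as.numeric(-(A %*% (dc * log(dc)))), V(g)$name)
}

#' Mapping entropy
#'
#' \eqn{ME(i) = -DC(i) \sum_{j \in \Gamma(i)} DC(j)}: a node's degree coupled
#' with its neighborhood degree mass.
#'
#' @inheritParams degree_centrality
#' @return named numeric score map (values are non-positive).
#' @export
mapping_entropy <- function(g) {
  g <- as_simple_named(g)
  dc <- degree_centrality(g)
  csn <- second_order_centrality(g)
  stats::setNames(-dc * csn, V(g)$name)
}

#' Second-order neighborhood betweenness entropy (SNB)
#'
#' \eqn{SNB(i) = -BC(i) \sum_{j \in \Gamma(i)} CSN(j)}: an entropy-style
#' fusion of a node's global path position (betweenness) with the two-hop
#' degree mass of its neighborhood. Returned signed, exactly as defined
#' (values are \eqn{\le 0}; SNB = 0 iff BC = 0). The orientation used when
#' fusing into the composite node value is chosen in [composite_value()].
#'
#' @inheritParams degree_centrality
#' @return named numeric score map.
#' @export
snb_entropy <- function(g) {
  g <- as_simple_named(g)
  bc <- betweenness_centrality(g)
  csn <- second_order_centrality(g)
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  stats::setNames(as.numeric(-bc * (A %*% csn)), V(g)$name)
}

#' Compute a named centrality measure
#'
#' Dispatcher over every score map the package provides, including the
#' fractal measures.
#'
#' @inheritParams degree_centrality
#' @param measure one of `"dc"`, `"csn"`, `"bc"`, `"cc"`, `"le"`, `"me"`,
#'   `"snb"`, `"ld"`, `"fld"`.
#' @return named numeric score map.
#' @export
centrality_scores <- function(g, measure = c("dc", "csn", "bc", "cc", "le",
                                             "me", "snb", "ld", "fld")) {
  measure <- match.arg(measure)
  switch(measure,
    dc  = degree_centrality(g),
    csn = second_order_centrality(g),
    bc  = betweenness_centrality(g),
    cc  = closeness_centrality(g),
    le  = local_entropy(g),
    me  = mapping_entropy(g),
    snb = snb_entropy(g),
    ld  = local_dimension(g),
    fld = fuzzy_local_dimension(g)
  )
}

#' Order nodes by descending score, ties by smaller label
#'
#' @param scores named numeric score map.
#' @return character vector of node labels, best first.
#' @export
rank_nodes <- function(scores) {
  names(scores)[order(-scores, label_rank(names(scores)))]
}
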