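#' Seeded Erdős–Rényi random graph
#'
#' G(n, p): every unordered node pair is an edge independently with
#' probability p. The raw draw is returned; apply [largest_component()] before
#' analysis, as for any input network. If a draw's largest component would
#' have fewer than 2 nodes, the graph is redrawn with an incremented derived
#' seed (with a message) so pipelines never receive degenerate input.
#'
#' @param n number of nodes (>= 2).
#' @param p edge probability in \[0, 1\].
#' @param rng_seed integer seed; the draw is deterministic given it.
#' @return an undirected igraph graph with labels "1".."n".
#' @examples
#' g <- er_graph(650, 0.01, rng_seed = 7)
#' igraph::gsize(g)
#' @export
er_graph <- function(n, p, rng_seed = 1) {
  if (n < 2) stop("n must be at least 2")
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  attempt <- 0L
  repeat {
    set.seed(derive_seed(rng_seed, attempt))
    g <- igraph::sample_gnp(n, p, directed = FALSE, loops = FALSE)
    V(g)$name <- as.character(seq_len(n))
    if (p == 0 || max(igraph::components(g)$csize) >= 2) break
    attempt <- attempt + 1L
    message(sprintf("degenerate ER draw; retrying with derived seed %d", attempt))
  }
  g
}

#' Canonical deterministic fixture graphs
#'
#' Small seedless graphs used throughout the test suite and examples:
#' \describe{
#'   \item{star}{K(1,k): center "1" joined to k leaves.}
#'   \item{path}{P_n: nodes "1".."n" in a line.}
#'   \item{cycle}{C_n: nodes "1".."n" in a ring.}
#'   \item{complete}{K_n.}
#'   \item{two_blobs}{two cliques of sizes `a` and `b` joined through a single
#'     bridge node adjacent to one member of each — the bridge is a planted
#'     high-betweenness target (the strict maximum when `a == b`; with
#'     unequal cliques the larger clique's attachment node can match it).}
#' }
#'
#' @param family one of `"star"`, `"path"`, `"cycle"`, `"complete"`,
#'   `"two_blobs"`.
#' @param n size for path/cycle/complete.
#' @param k leaf count for the star.
#' @param a,b clique sizes for two_blobs.
#' @return an undirected igraph graph with character labels.
#' @export
fixture_graph <- function(family = c("star", "path", "cycle", "complete",
                                     "two_blobs"),
                          n = 10, k = 4, a = 5, b = 5) {
  family <- match.arg(family)
  g <- switch(family,
    star     = igraph::make_star(k + 1, mode = "undirected", center = 1),
    path     = igraph::make_ring(n, circular = FALSE),
    cycle    = igraph::make_ring(n),
    complete = igraph::make_full_graph(n),
    two_blobs = {
      ga <- igraph::make_full_graph(a)
      gb <- igraph::make_full_graph(b)
      g2 <- igraph::disjoint_union(ga, gb)
      g2 <- igraph::add_vertices(g2, 1)            # the bridge
      igraph::add_edges(g2, c(a + b + 1, 1, a + b + 1, a + 1))
    }
  )
  V(g)$name <- as.character(seq_len(gorder(g)))
  if (family == "two_blobs") {
    # name the bridge last so blob labels stay 1..a and a+1..a+b
    V(g)$name[a + b + 1] <- "bridge"
  }
  as_simple_named(g)
}
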