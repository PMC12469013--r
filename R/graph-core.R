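#' @importFrom igraph V E gorder gsize vcount ecount
#' @importFrom igraph "V<-"
NULL

#' Order node labels deterministically
#'
#' All tie-breaking in the package ("smaller label first") uses this ordering:
#' numeric if every label parses as a number (so node "9" precedes node "10",
#' matching how network datasets number their vertices), lexicographic
#' otherwise.
#'
#' @param labels character vector of node labels.
#' @return integer permutation ordering `labels`.
#' @keywords internal
label_order <- function(labels) {
  num <- suppressWarnings(as.numeric(labels))
  if (!anyNA(num)) order(num, labels) else order(labels)
}

#' Rank of each label under the package's deterministic label ordering
#' @keywords internal
#' @noRd
label_rank <- function(labels) {
  r <- integer(length(labels))
  r[label_order(labels)] <- seq_along(labels)
  r
}

#' Ensure an igraph object is a named, simple, undirected graph
#' @keywords internal
#' @noRd
as_simple_named <- function(g) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "collapse")
  if (is.null(V(g)$name)) V(g)$name <- as.character(seq_len(gorder(g)))
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Read an undirected network from an edge list
#'
#' Parses a plain-text edge list: one edge per line, two node labels separated
#' by whitespace or a comma (auto-detected). Lines starting with `#` or `%`
#' and blank lines are skipped. Duplicate edges (in either orientation)
#' collapse to a single undirected edge; self-loops are dropped with a message
#' reporting how many.
#'
#' @param file path to an edge-list file, or a character vector of lines.
#' @return an undirected, simple [igraph::igraph] graph with character vertex
#'   names. Node labels are kept verbatim (never reinterpreted as numbers).
#' @examples
#' g <- read_edge_list(c("1 2", "2 3", "3 1"))
#' igraph::gorder(g)
#' @export
read_edge_list <- function(file) {
  lines <- if (length(file) == 1L && !grepl("[\n ]", file) && file.exists(file)) {
    readLines(file, warn = FALSE)
  } else {
    as.character(file)
  }
  keep <- !grepl("^\\s*(#|%)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) stop("empty edge list: no data lines found")
  ends <- matrix("", nrow = length(idx), ncol = 2L)
  for (k in seq_along(idx)) {
    ln <- trimws(lines[idx[k]])
    toks <- if (grepl(",", ln)) {
      trimws(strsplit(ln, ",", fixed = TRUE)[[1]])
    } else {
      strsplit(ln, "\\s+")[[1]]
    }
    toks <- toks[nzchar(toks)]
    if (length(toks) < 2L) {
      stop(sprintf("malformed edge list line %d: %s", idx[k], lines[idx[k]]))
    }
    ends[k, ] <- toks[1:2]
  }
  loops <- sum(ends[, 1] == ends[, 2])
  if (loops > 0) message(sprintf("dropped %d self-loop(s)", loops))
  g <- igraph::graph_from_edgelist(ends, directed = FALSE)
  as_simple_named(g)
}

#' Read a network from an edge list or GML file
#'
#' @param file path to the network file.
#' @param format `"edgelist"` or `"gml"`; `"auto"` picks GML for a `.gml`
#'   extension.
#' @return an undirected simple igraph graph with character vertex names.
#' @export
read_network <- function(file, format = c("auto", "edgelist", "gml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gml$", file, ignore.case = TRUE)) "gml" else "edgelist"
  }
  if (format == "gml") {
    g <- igraph::read_graph(file, format = "gml")
    if (is.null(V(g)$name) && !is.null(V(g)$label)) V(g)$name <- as.character(V(g)$label)
    if (is.null(V(g)$name) && !is.null(V(g)$id)) V(g)$name <- as.character(V(g)$id)
    as_simple_named(g)
  } else {
    read_edge_list(file)
  }
}

#' Write a graph as a two-column edge list
#'
#' @param g an igraph graph.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_edge_list <- function(g, file) {
  g <- as_simple_named(g)
  el <- igraph::as_edgelist(g, names = TRUE)
  writeLines(paste(el[, 1], el[, 2]), file)
  invisible(file)
}

#' Extract the largest connected component
#'
#' Preprocessing keeps only the dominant connected component; every centrality
#' and spring-model routine in the package expects its output. Size ties are
#' broken toward the component containing the smallest node label.
#'
#' @param g an igraph graph.
#' @return the induced subgraph on the largest component.
#' @export
largest_component <- function(g) {
  g <- as_simple_named(g)
  if (gorder(g) == 0L) stop("empty graph")
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # tie: component holding the smallest member label wins
    first_lab <- vapply(best, function(ci) {
      labs <- V(g)$name[comp$membership == ci]
      labs[label_order(labs)][1]
    }, character(1))
    best <- best[label_order(first_lab)[1]]
  }
  igraph::induced_subgraph(g, which(comp$membership == best))
}

#' All-pairs shortest-path hop counts
#'
#' BFS hop distances between every pair of nodes, as a dense symmetric matrix
#' with node labels as dimnames and the network diameter attached as
#' attribute `"diameter"`.
#'
#' @param g a connected igraph graph.
#' @return numeric matrix of hop counts.
#' @export
all_pairs_distances <- function(g) {
  g <- as_simple_named(g)
  if (!igraph::is_connected(g)) {
    stop("graph is disconnected; apply largest_component() first")
  }
  d <- igraph::distances(g, algorithm = "unweighted")
  attr(d, "diameter") <- as.integer(max(d))
  d
}

#' Topological summary of a network
#'
#' Node and edge counts, average degree \eqn{k = 2E/N}, maximum degree, average
#' shortest path length over unordered distinct pairs, and diameter.
#'
#' @param g a connected igraph graph.
#' @return a one-row data.frame with columns `n_nodes`, `n_edges`,
#'   `avg_degree`, `max_degree`, `avg_path`, `diameter`.
#' @export
network_summary <- function(g) {
  g <- as_simple_named(g)
  if (!igraph::is_connected(g)) {
    stop("graph is disconnected; apply largest_component() first")
  }
  dm <- all_pairs_distances(g)
  n <- gorder(g)
  deg <- igraph::degree(g)
  data.frame(
    n_nodes    = n,
    n_edges    = gsize(g),
    avg_degree = 2 * gsize(g) / n,
    max_degree = as.integer(max(deg)),
    avg_path   = sum(dm[upper.tri(dm)]) / (n * (n - 1) / 2),
    diameter   = attr(dm, "diameter")
  )
}
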