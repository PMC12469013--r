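# Brute-force oracles, deliberately independent of the implementation path
# (and of igraph's algorithms): everything works on a plain adjacency matrix.

# adjacency matrix of a graph, built from its raw edge list only
adj_matrix <- function(g) {
  labs <- igraph::V(g)$name
  n <- length(labs)
  A <- matrix(0, n, n, dimnames = list(labs, labs))
  el <- igraph::as_edgelist(g, names = TRUE)
  for (e in seq_len(nrow(el))) {
    A[el[e, 1], el[e, 2]] <- 1
    A[el[e, 2], el[e, 1]] <- 1
  }
  A
}

# Floyd-Warshall all-pairs distances
oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n, dimnames = dimnames(A))
  diag(D) <- 0
  D[A == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

# geodesic counts N[j, k] by dynamic programming over increasing distance
oracle_path_counts <- function(A, D) {
  n <- nrow(A)
  P <- matrix(0, n, n, dimnames = dimnames(A))
  diag(P) <- 1
  for (j in seq_len(n)) {
    for (dd in sort(unique(D[j, D[j, ] > 0]))) {
      for (k in which(D[j, ] == dd)) {
        pred <- which(A[, k] == 1 & D[j, ] == dd - 1)
        P[j, k] <- sum(P[j, pred])
      }
    }
  }
  P
}

# raw betweenness over unordered pairs, endpoints excluded
oracle_betweenness <- function(A) {
  D <- oracle_distances(A)
  P <- oracle_path_counts(A, D)
  n <- nrow(A)
  bc <- numeric(n)
  for (j in seq_len(n - 1)) {
    for (k in (j + 1):n) {
      for (i in seq_len(n)) {
        if (i == j || i == k) next
        if (D[j, i] + D[i, k] == D[j, k]) {
          bc[i] <- bc[i] + P[j, i] * P[i, k] / P[j, k]
        }
      }
    }
  }
  stats::setNames(bc, rownames(A))
}

oracle_degree <- function(A) rowSums(A)
oracle_csn <- function(A) {
  stats::setNames(as.numeric(A %*% rowSums(A)), rownames(A))
}
oracle_closeness <- function(A) {
  D <- oracle_distances(A)
  (nrow(A) - 1) / rowSums(D)
}
oracle_le <- function(A) {
  dc <- rowSums(A)
  stats::setNames(vapply(seq_len(nrow(A)), function(i) {
    nb <- which(A[i, ] == 1)
    -sum(dc[nb] * log(dc[nb]))
  }, numeric(1)), rownames(A))
}
oracle_me <- function(A) {
  stats::setNames(-rowSums(A) * as.numeric(A %*% rowSums(A)), rownames(A))
}
oracle_snb <- function(A) {
  csn <- oracle_csn(A)
  stats::setNames(-oracle_betweenness(A) * as.numeric(A %*% csn), rownames(A))
}

# a random connected labeled graph on <= nmax nodes
random_connected_graph <- function(seed, nmax = 10) {
  set.seed(seed)
  repeat {
    n <- sample(4:nmax, 1)
    g <- igraph::sample_gnp(n, stats::runif(1, 0.25, 0.7))
    if (igraph::is_connected(g) && igraph::gsize(g) >= n - 1) {
      igraph::V(g)$name <- as.character(seq_len(n))
      return(g)
    }
  }
}

# exact mean infected-count trajectory of the synchronous SI chain on a
# complete graph: the infected count is a Markov chain,
# i -> i + Binomial(N - i, 1 - (1-beta)^i); propagate its distribution.
oracle_k_complete_si_mean <- function(N, beta, i0, t_max) {
  P <- matrix(0, N, N)
  for (i in seq_len(N)) {
    s <- N - i
    if (s == 0) { P[i, N] <- 1; next }
    p <- 1 - (1 - beta)^i
    P[i, i + (0:s)] <- stats::dbinom(0:s, s, p)
  }
  v <- rep(0, N); v[i0] <- 1
  out <- numeric(t_max + 1)
  out[1] <- i0
  for (t in seq_len(t_max)) {
    v <- as.vector(v %*% P)
    out[t + 1] <- sum(v * seq_len(N))
  }
  out
}

expect_scores_equal <- function(x, y, tol = 1e-9) {
  expect_equal(as.numeric(x[sort(names(x))]),
               as.numeric(y[sort(names(x))]),
               tolerance = tol, ignore_attr = TRUE)
}

minmax_oracle <- function(x) {
  if (max(x) == min(x)) return(rep(0, length(x)))
  (x - min(x)) / (max(x) - min(x))
}
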