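# replicate r of a run gets its own sub-stream so replicates are independent
# and individually reproducible; kept well below 2^31
derive_seed <- function(rng_seed, r) {
  (as.integer(rng_seed) %% 1000003L) * 1009L + as.integer(r)
}

#' Stochastic SI spreading on a network
#'
#' Discrete-time synchronous susceptible-infected process: at every step each
#' infected node independently infects each susceptible neighbor with
#' probability `beta`; there is no recovery, so infected sets are nested over
#' time and \eqn{S(t) + I(t) = N} at every step. Curves are averaged over
#' `runs` replicates, each with its own derived seed.
#'
#' @param g a connected igraph graph.
#' @param beta per-contact per-step infection probability in \[0, 1\].
#' @param seeds character vector of initially infected node labels.
#' @param t_max number of steps to simulate.
#' @param runs number of replicates to average over.
#' @param rng_seed integer seed; fixing it makes the result bit-reproducible.
#' @return a `data.frame` with columns `t` (0..t_max), `mean_infected`, and
#'   `mean_susceptible`; attribute `"per_run"` holds the runs x (t_max+1)
#'   matrix of infected counts.
#' @export
si_simulate <- function(g, beta, seeds, t_max = 30, runs = 100, rng_seed = 1) {
  g <- as_simple_named(g)
  if (beta < 0 || beta > 1) stop("beta must lie in [0, 1]")
  if (length(seeds) == 0) stop("seed set must be non-empty")
  labs <- V(g)$name
  if (!all(seeds %in% labs)) stop("seeds must be node labels of the graph")
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  n <- length(labs)
  seed_vec <- as.numeric(labs %in% seeds)
  per_run <- matrix(0, nrow = runs, ncol = t_max + 1)
  for (r in seq_len(runs)) {
    set.seed(derive_seed(rng_seed, r))
    inf <- seed_vec
    per_run[r, 1] <- sum(inf)
    for (t in seq_len(t_max)) {
      k <- as.numeric(A %*% inf)              # infected contacts per node
      p <- 1 - (1 - beta)^k                   # prob a susceptible converts
      new_inf <- (inf == 0) & (stats::runif(n) < p)
      inf[new_inf] <- 1
      ni <- sum(inf)
      stopifnot(ni + (n - ni) == n)           # conservation S + I = N
      per_run[r, t + 1] <- ni
    }
  }
  out <- data.frame(
    t = 0:t_max,
    mean_infected = colMeans(per_run),
    mean_susceptible = n - colMeans(per_run)
  )
  attr(out, "per_run") <- per_run
  out
}

#' Mean-field SI logistic solution
#'
#' Closed-form solution of the uniform-mixing SI equations
#' \eqn{dI/dt = \beta S I / N}, \eqn{S = N - I}:
#' \deqn{I(t) = \frac{N}{1 + \frac{N - I_0}{I_0} e^{-\beta t}}.}
#' I(0) = I0 and I(t) tends to N as t grows (the whole population is
#' eventually infected); the inflection sits where I = N/2, at
#' \eqn{t = \log((N - I_0)/I_0)/\beta}.
#'
#' @param beta infection rate.
#' @param n total population N.
#' @param i0 initial infected count, 0 < i0 < n.
#' @param t numeric vector of times.
#' @return `data.frame` with columns `t`, `infected`, `susceptible`.
#' @export
si_ode <- function(beta, n, i0, t) {
  if (i0 <= 0) stop("i0 must be positive")
  if (i0 >= n) stop("i0 must be below the population size")
  infected <- n / (1 + (n - i0) / i0 * exp(-beta * t))
  data.frame(t = t, infected = infected, susceptible = n - infected)
}

#' Empirical per-node infectivity
#'
#' Seeds the SI process at every node in turn and reports the mean infected
#' count after `t_obs` steps over `runs` replicates — the realized spreading
#' power used as ground truth when validating centrality rankings. All
#' single-seed epidemics of one replicate are simulated simultaneously
#' (one column per seed), each column an independent realization.
#'
#' @inheritParams si_simulate
#' @param t_obs observation step (default 10).
#' @return named numeric score map: node -> mean infected count at `t_obs`.
#' @export
node_infectivity <- function(g, beta = 0.1, t_obs = 10, runs = 100,
                             rng_seed = 1) {
  g <- as_simple_named(g)
  if (beta < 0 || beta > 1) stop("beta must lie in [0, 1]")
  labs <- V(g)$name
  n <- length(labs)
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  acc <- numeric(n)
  for (r in seq_len(runs)) {
    set.seed(derive_seed(rng_seed, r))
    inf <- diag(n)                 # column s: epidemic seeded at node s
    for (t in seq_len(t_obs)) {
      k <- as.matrix(A %*% inf)
      p <- 1 - (1 - beta)^k
      new_inf <- (inf == 0) & (matrix(stats::runif(n * n), n, n) < p)
      inf[new_inf] <- 1
    }
    acc <- acc + colSums(inf)
  }
  stats::setNames(acc / runs, labs)
}

#' Kendall rank correlation (tau-a)
#'
#' \eqn{\tau = (C - D) / (0.5\,n(n-1))} over all unordered pairs: C counts
#' concordant pairs, D discordant ones; pairs tied in either input count for
#' neither, while the all-pairs denominator is retained (tau-a). `variant =
#' "b"` instead delegates to [stats::cor()] for the tie-corrected tau-b.
#'
#' @param a,b numeric score maps over the same nodes (names matched when
#'   present).
#' @param variant `"a"` (default) or `"b"`.
#' @return a list of class `"kendall_tau"` with elements `tau`, `C`, `D`, `n`,
#'   `variant`.
#' @export
kendall_tau <- function(a, b, variant = c("a", "b")) {
  variant <- match.arg(variant)
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b))) stop("score maps cover different nodes")
    b <- b[names(a)]
  } else if (length(a) != length(b)) {
    stop("rankings must have equal length")
  }
  n <- length(a)
  if (n < 2) stop("need at least two observations")
  sa <- sign(outer(a, a, "-"))
  sb <- sign(outer(b, b, "-"))
  prod <- sa * sb
  up <- upper.tri(prod)
  C <- sum(prod[up] > 0)
  D <- sum(prod[up] < 0)
  tau <- if (variant == "a") {
    (C - D) / (0.5 * n * (n - 1))
  } else {
    unname(stats::cor(as.numeric(a), as.numeric(b), method = "kendall"))
  }
  structure(list(tau = tau, C = C, D = D, n = n, variant = variant),
            class = "kendall_tau")
}

#' @export
print.kendall_tau <- function(x, ...) {
  cat(sprintf("Kendall tau-%s = %.4f  (C = %d, D = %d, n = %d)\n",
              x$variant, x$tau, x$C, x$D, x$n))
  invisible(x)
}

#' Jaccard overlap of two top-k node sets
#'
#' \eqn{|top_k(a) \cap top_k(b)| / |top_k(a) \cup top_k(b)|}; 1 means the two
#' methods agree on the k most important nodes, 0 means no overlap.
#'
#' @param a,b rankings: either character vectors of node labels (best first),
#'   `data.frame`s with a `node` column as returned by [snefld_rank()], or
#'   named score maps (ranked by descending score, ties by smaller label).
#' @param k set size (default 10).
#' @return Jaccard coefficient in \[0, 1\].
#' @export
jaccard_topk <- function(a, b, k = 10) {
  if (k <= 0) stop("k must be positive")
  topk <- function(x) {
    if (is.data.frame(x)) x <- x$node
    if (!is.null(names(x)) && is.numeric(x)) x <- rank_nodes(x)
    if (k > length(x)) stop("k exceeds ranking length")
    x[seq_len(k)]
  }
  ta <- topk(a); tb <- topk(b)
  length(intersect(ta, tb)) / length(union(ta, tb))
}

#' Connectivity under targeted node removal
#'
#' Removes nodes in ranking order (most important first) and tracks, at each
#' removal fraction, the size of the largest remaining connected component
#' relative to the original node count, plus the raw number of components.
#' A steeper collapse means the ranking found nodes more critical to the
#' network's integrity.
#'
#' @param g a connected igraph graph.
#' @param order ranking covering all nodes: character vector of labels, a
#'   ranking `data.frame` with a `node` column, or a named score map.
#' @param fractions removal fractions in \[0, 1\].
#' @return `data.frame` with columns `fraction`, `removed`, `connectivity`
#'   (giant component size / original N; 0 once all nodes are gone) and
#'   `components`.
#' @export
robustness_curve <- function(g, order, fractions = seq(0, 1, by = 0.01)) {
  g <- as_simple_named(g)
  if (is.data.frame(order)) order <- order$node
  if (!is.null(names(order)) && is.numeric(order)) order <- rank_nodes(order)
  labs <- V(g)$name
  if (!setequal(order, labs)) stop("order must cover exactly the graph's nodes")
  n <- length(labs)
  out <- data.frame(fraction = fractions, removed = NA_integer_,
                    connectivity = NA_real_, components = NA_integer_)
  for (i in seq_along(fractions)) {
    nrem <- min(n, floor(fractions[i] * n))
    out$removed[i] <- nrem
    if (nrem >= n) {
      out$connectivity[i] <- 0
      out$components[i] <- 0L
      next
    }
    sub <- igraph::delete_vertices(g, order[seq_len(nrem)])
    comp <- igraph::components(sub)
    out$connectivity[i] <- max(comp$csize) / n
    out$components[i] <- comp$no
  }
  out
}
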