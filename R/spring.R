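#' Min-max normalize a score map to [0, 1]
#'
#' A constant map normalizes to all zeros: a feature with no spread carries no
#' ranking information, so its channel contributes nothing.
#' @keywords internal
#' @noRd
minmax <- function(x) {
  rng <- range(x)
  if (rng[2] - rng[1] <= 0) return(stats::setNames(rep(0, length(x)), names(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Composite node value from SNB and FLD
#'
#' \eqn{L_i = \lambda\,\mathrm{norm}(SNB_i) + (1-\lambda)\,\mathrm{norm}(FLD_i)}
#' with min-max normalization of each channel to [0, 1].
#'
#' Both channels are oriented toward importance before mixing:
#' \describe{
#'   \item{SNB}{SNB is defined as \eqn{-BC(i)\sum_j CSN(j) \le 0}, so min-max
#'     of the signed values would rank high-betweenness hubs *lowest*. The
#'     default `orientation = "magnitude"` uses \eqn{|SNB| = BC \cdot \sum
#'     CSN}; `"signed"` keeps the literal signed formula for sensitivity
#'     analysis.}
#'   \item{FLD}{a node's ball-growth exponent saturates early around hubs, so
#'     low local dimension marks a structurally central node (the convention
#'     local-dimension rankings use). The default `fld_orientation =
#'     "locality"` therefore uses the *complement* of the normalized
#'     dimension, `1 - minmax(FLD)`; `"dimension"` feeds the raw exponent in
#'     unchanged.}
#' }
#'
#' @param snb score map from [snb_entropy()].
#' @param fld score map from [fuzzy_local_dimension()].
#' @param lambda weight of the SNB channel, in \[0, 1\] (default 0.5: equal
#'   weight to the entropy and fractal channels).
#' @param orientation SNB channel orientation, `"magnitude"` (default) or
#'   `"signed"`.
#' @param fld_orientation FLD channel orientation, `"locality"` (default) or
#'   `"dimension"`.
#' @return named numeric score map of composite values L in \[0, 1\].
#' @export
composite_value <- function(snb, fld, lambda = 0.5,
                            orientation = c("magnitude", "signed"),
                            fld_orientation = c("locality", "dimension")) {
  orientation <- match.arg(orientation)
  fld_orientation <- match.arg(fld_orientation)
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  stopifnot(setequal(names(snb), names(fld)))
  fld <- as.numeric(fld[names(snb)])
  s <- if (orientation == "magnitude") abs(snb) else snb
  f <- minmax(fld)
  # a constant channel stays all-zero rather than flipping to all-one
  if (fld_orientation == "locality" && any(f > 0)) f <- 1 - f
  stats::setNames(lambda * minmax(s) + (1 - lambda) * f, names(snb))
}

#' Full-range improved spring model (ISM)
#'
#' Treats the influence between nodes i and j as a scalar elastic force
#' \eqn{L_i L_j (d - d_{ij})}, where d is the network diameter and
#' \eqn{d - d_{ij}} the spring deformation, and sums it over all partners:
#' \deqn{ISM(v_i) = \sum_{j \ne i} L_i L_j (d - d_{ij}).}
#'
#' @param dm distance matrix from [all_pairs_distances()].
#' @param L named score map of composite node values (>= 0), e.g. from
#'   [composite_value()].
#' @return named numeric score map of ISM values.
#' @export
ism_full <- function(dm, L) {
  L <- L[rownames(dm)]
  stopifnot(!anyNA(L), all(L >= 0))
  d <- max(dm)
  W <- d - dm
  diag(W) <- 0        # self-pairs excluded (d - d_ii = d would inject L_i^2 d)
  stats::setNames(as.numeric(L * (W %*% L)), rownames(dm))
}

#' Per-node influence range
#'
#' Balances node i's force against the force of the node farthest from it:
#' with \eqn{v_l} the farthest node (ties to the smaller label) and
#' \eqn{d_l = d_{il}},
#' \deqn{R_i = \frac{(L_i - L_l)\,d + L_l\,d_l}{L_l + L_i},}
#' clamped to \eqn{[1, d]}. When \eqn{L_i = L_l} this is \eqn{d_l/2}; a
#' dominant node (\eqn{L_i \gg L_l}, \eqn{d_l = d}) reaches the whole network.
#' Nodes with \eqn{L_i + L_l = 0} have no force to balance and default to
#' range 1 with a warning.
#'
#' @inheritParams ism_full
#' @return named numeric score map of ranges in \[1, d\].
#' @export
influence_range <- function(dm, L) {
  L <- L[rownames(dm)]
  stopifnot(!anyNA(L), all(L >= 0))
  labs <- rownames(dm)
  lr <- label_rank(labs)
  d <- max(dm)
  n <- nrow(dm)
  R <- numeric(n)
  zero_force <- 0L
  for (i in seq_len(n)) {
    drow <- dm[i, ]
    far <- which(drow == max(drow))
    l <- far[order(lr[far])][1]
    Li <- L[i]; Ll <- L[l]; dl <- drow[l]
    if (Li + Ll == 0) {
      R[i] <- 1
      zero_force <- zero_force + 1L
    } else {
      R[i] <- min(max(((Li - Ll) * d + Ll * dl) / (Ll + Li), 1), d)
    }
  }
  if (zero_force > 0) {
    warning(sprintf("%d node(s) with zero composite value: influence range defaulted to 1",
                    zero_force))
  }
  stats::setNames(R, labs)
}

#' Range-restricted improved spring model
#'
#' As [ism_full()], but node i only sums forces over partners within its own
#' influence range: \eqn{ISM(v_i) = \sum_{j \ne i,\, d_{ij} \le R_i}
#' L_i L_j (d - d_{ij})}. With all \eqn{R_i \ge d} this reduces exactly to the
#' full-range model.
#'
#' @inheritParams ism_full
#' @param R named score map of influence ranges from [influence_range()].
#' @return named numeric score map of ISM values.
#' @export
ism_ranged <- function(dm, L, R) {
  L <- L[rownames(dm)]
  R <- R[rownames(dm)]
  stopifnot(!anyNA(L), all(L >= 0), !anyNA(R))
  d <- max(dm)
  W <- d - dm
  diag(W) <- 0
  W[sweep(dm, 1, R, ">")] <- 0   # row i keeps only partners with d_ij <= R_i
  stats::setNames(as.numeric(L * (W %*% L)), rownames(dm))
}

#' Greedy ranking with neighbor attenuation
#'
#' Iteratively selects the unselected node with the largest current value
#' (ties to the smaller label), freezes its score, and multiplies each
#' *unselected* neighbor's current value by the attenuation factor
#' \deqn{1 - \frac{ISM(v_i)}{ISM(v_i) + \sum_{u \in \Gamma(i)} ISM(v_u)},}
#' evaluated on the current (possibly already attenuated) values. The factor
#' lies in (0, 1] and equals 1 exactly when the selected node's value is 0,
#' so zero-influence nodes suppress nothing. This damping of a chosen
#' spreader's neighborhood counters the rich-club tendency of top spreaders
#' to cluster.
#'
#' @param g a connected igraph graph.
#' @param ism named non-negative score map, typically from [ism_ranged()].
#' @return a `data.frame` with columns `rank`, `node`, `score` (the value at
#'   selection time) and attribute `"initial"` (the input map).
#' @export
snefld_rank <- function(g, ism) {
  g <- as_simple_named(g)
  labs <- V(g)$name
  stopifnot(setequal(names(ism), labs))
  cur <- as.numeric(ism[labs])
  stopifnot(all(cur >= 0))
  lr <- label_rank(labs)
  adj <- igraph::adjacent_vertices(g, V(g))
  n <- length(labs)
  selected <- logical(n)
  ord <- integer(n)
  score <- numeric(n)
  for (step in seq_len(n)) {
    cand <- which(!selected)
    i <- cand[order(-cur[cand], lr[cand])][1]
    ord[step] <- i
    score[step] <- cur[i]
    selected[i] <- TRUE
    nb <- as.integer(adj[[i]])
    if (length(nb) > 0 && cur[i] > 0) {
      denom <- cur[i] + sum(cur[nb])   # neighbor values at selection time
      factor <- 1 - cur[i] / denom
      open <- nb[!selected[nb]]
      cur[open] <- cur[open] * factor
    }
  }
  out <- data.frame(rank = seq_len(n), node = labs[ord], score = score,
                    stringsAsFactors = FALSE)
  attr(out, "initial") <- ism[labs]
  out
}

#' SNEFLD-SM key-node ranking, end to end
#'
#' Runs the whole method on a connected graph: second-order neighborhood
#' betweenness entropy, fuzzy local dimension, composite node value
#' (weight `lambda`), full spring forces, per-node influence range,
#' range-restricted spring forces, and the greedy attenuation ranking.
#'
#' @param g a connected igraph graph (apply [largest_component()] first if
#'   needed).
#' @inheritParams composite_value
#' @return a `data.frame` with columns `rank`, `node`, `score`, `L`, `R`,
#'   `ism` (the pre-attenuation range-restricted spring value), ordered by
#'   selection; attribute `"config"` records the configuration.
#' @examples
#' g <- fixture_graph("two_blobs", a = 5, b = 5)
#' snefld_sm(g)
#' @export
snefld_sm <- function(g, lambda = 0.5, orientation = c("magnitude", "signed"),
                      fld_orientation = c("locality", "dimension")) {
  orientation <- match.arg(orientation)
  fld_orientation <- match.arg(fld_orientation)
  g <- as_simple_named(g)
  if (!igraph::is_connected(g)) {
    stop("graph is disconnected; apply largest_component() first")
  }
  dm <- all_pairs_distances(g)
  snb <- snb_entropy(g)
  fld <- suppressWarnings(fuzzy_local_dimension(g, dm))
  L <- composite_value(snb, fld, lambda = lambda, orientation = orientation,
                       fld_orientation = fld_orientation)
  R <- suppressWarnings(influence_range(dm, L))
  ism <- ism_ranged(dm, L, R)
  ranked <- snefld_rank(g, ism)
  ranked$L <- as.numeric(L[ranked$node])
  ranked$R <- as.numeric(R[ranked$node])
  ranked$ism <- as.numeric(ism[ranked$node])
  attr(ranked, "config") <- list(lambda = lambda, orientation = orientation,
                                 fld_orientation = fld_orientation)
  ranked
}
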