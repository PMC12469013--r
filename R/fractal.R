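#' Gaussian box membership
#'
#' Fuzzy degree to which a node at hop distance `d` belongs to a box of size
#' `eps` around a center: \eqn{A(d, \varepsilon) = \exp(-d^2/\varepsilon^2)}.
#' Always in (0, 1]; equals 1 at the center and decays with distance, so
#' nearby nodes contribute more to the center's fuzzy count.
#'
#' @param d non-negative hop distance(s).
#' @param eps positive box size.
#' @return membership value(s) in (0, 1].
#' @export
box_membership <- function(d, eps) {
  if (any(eps <= 0)) stop("eps must be positive")
  if (any(d < 0)) stop("distances must be non-negative")
  exp(-(d^2) / eps^2)
}

#' Fuzzy number of nodes in a box
#'
#' Membership-weighted count of the nodes within hop radius `rt` of `center`,
#' with box size coupled to the radius (eps = rt) and the center included
#' with membership 1:
#' \deqn{N_i(r_t) = \sum_{j : d_{ij} \le r_t} \exp(-d_{ij}^2 / r_t^2).}
#'
#' @param dm distance matrix from [all_pairs_distances()].
#' @param center node label (or index) of the box center.
#' @param rt integer radius, 1 <= rt <= max distance from the center.
#' @return fuzzy node count (real).
#' @export
fuzzy_box_count <- function(dm, center, rt) {
  drow <- dm[center, ]
  dimax <- max(drow)
  if (rt < 1 || rt > dimax) {
    stop(sprintf("rt must lie in [1, %d] for this center", dimax))
  }
  inside <- drow <= rt
  sum(box_membership(drow[inside], rt))
}

# least-squares slope of log(count) vs log(radius); degenerate single-radius
# centers (adjacent to every node) fall back to 0
.loglog_slopes <- function(dm, count_fun, label) {
  n <- nrow(dm)
  vals <- numeric(n)
  pts <- integer(n)
  rss <- numeric(n)
  degenerate <- character(0)
  for (i in seq_len(n)) {
    dimax <- max(dm[i, ])
    if (dimax < 2) {
      vals[i] <- 0
      pts[i] <- 1L
      degenerate <- c(degenerate, rownames(dm)[i])
      next
    }
    r <- seq_len(dimax)
    y <- log(vapply(r, function(rt) count_fun(i, rt), numeric(1)))
    x <- log(r)
    fit <- stats::lm.fit(cbind(1, x), y)
    vals[i] <- fit$coefficients[2]
    pts[i] <- length(r)
    rss[i] <- sum(fit$residuals^2)
  }
  if (length(degenerate) > 0) {
    warning(sprintf(
      "%d node(s) adjacent to the whole network have a single radius; %s set to 0 for: %s",
      length(degenerate), label, paste(utils::head(degenerate, 5), collapse = ", ")
    ))
  }
  out <- stats::setNames(vals, rownames(dm))
  attr(out, "diagnostics") <- data.frame(
    node = rownames(dm), points = pts, rss = rss, row.names = NULL
  )
  out
}

#' Local (fractal) dimension
#'
#' Per-node growth exponent of the crisp ball size: the least-squares slope of
#' \eqn{\log B_i(r)} against \eqn{\log r} for r = 1..d_i^{max}, where
#' \eqn{B_i(r)} counts the nodes within r hops of i (center included).
#' Nodes adjacent to the entire network have a single radius and receive 0
#' with a warning.
#'
#' @param g a connected igraph graph.
#' @param dm optional precomputed [all_pairs_distances()] matrix.
#' @return named numeric score map with a `"diagnostics"` attribute
#'   (points used and residual sum of squares per node).
#' @export
local_dimension <- function(g, dm = NULL) {
  g <- as_simple_named(g)
  if (is.null(dm)) dm <- all_pairs_distances(g)
  .loglog_slopes(dm, function(i, rt) sum(dm[i, ] <= rt), "LD")
}

#' Fuzzy local dimension (FLD)
#'
#' Per-node growth exponent of the fuzzy ball size: for each node, sweep the
#' radius rt from 1 to the node's eccentricity, compute the fuzzy box count
#' [fuzzy_box_count()] with box size eps = rt, and fit \eqn{\log N_i(r_t)}
#' against \eqn{\log r_t} by ordinary least squares. The Gaussian membership
#' downweights the shell of each ball, sharpening the distinction between
#' dense cores and peripheral nodes relative to [local_dimension()].
#'
#' @inheritParams local_dimension
#' @return named numeric score map with a `"diagnostics"` attribute.
#' @export
fuzzy_local_dimension <- function(g, dm = NULL) {
  g <- as_simple_named(g)
  if (is.null(dm)) dm <- all_pairs_distances(g)
  .loglog_slopes(dm, function(i, rt) {
    drow <- dm[i, ]
    inside <- drow <= rt
    sum(exp(-(drow[inside]^2) / rt^2))
  }, "FLD")
}
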