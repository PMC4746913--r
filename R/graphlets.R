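#' Exact graphlet census of an undirected graph (brute force)
#'
#' Counts the connected induced 3- and 4-node subgraph classes G0-G8
#' (G0 edge, G1 2-path, G2 triangle, G3 4-path, G4 3-star, G5 4-cycle,
#' G6 tailed triangle, G7 diamond, G8 complete 4-graph) by enumerating all
#' node triples and quadruples and classifying each induced subgraph by its
#' edge count and degree sequence. This enumerator is deliberately simple
#' and serves as the reference oracle for the incremental C++ counter; use
#' it on small graphs only.
#'
#' @param edges two-column matrix or data frame of undirected edges (node
#'   labels of any atomic type). Duplicate and reversed pairs collapse to a
#'   single edge; self-loops are rejected.
#' @param nodes optional vector of node labels including isolated nodes.
#' @return Named integer vector `G0`..`G8`.
#' @examples
#' count_graphlets(rbind(c(1, 2), c(1, 3), c(1, 4)))  # claw: G4 = 1
#' @export
count_graphlets <- function(edges, nodes = NULL) {
  edges <- as.matrix(edges)
  if (nrow(edges) > 0 && any(edges[, 1] == edges[, 2]))
    stop("self-loops are not allowed")
  labels <- unique(c(as.vector(edges[, 1:2]), as.vector(nodes)))
  n <- length(labels)
  counts <- stats::setNames(integer(9), paste0("G", 0:8))
  if (n == 0L) return(counts)
  A <- matrix(FALSE, n, n)
  if (nrow(edges) > 0) {
    i <- match(edges[, 1], labels)
    j <- match(edges[, 2], labels)
    A[cbind(i, j)] <- TRUE
    A[cbind(j, i)] <- TRUE
  }
  counts["G0"] <- sum(A) / 2L

  if (n >= 3L) {
    tr <- utils::combn(n, 3L)
    e3 <- A[cbind(tr[1, ], tr[2, ])] + A[cbind(tr[1, ], tr[3, ])] +
      A[cbind(tr[2, ], tr[3, ])]
    counts["G1"] <- sum(e3 == 2L)
    counts["G2"] <- sum(e3 == 3L)
  }
  if (n >= 4L) {
    q <- utils::combn(n, 4L)
    e12 <- A[cbind(q[1, ], q[2, ])]; e13 <- A[cbind(q[1, ], q[3, ])]
    e14 <- A[cbind(q[1, ], q[4, ])]; e23 <- A[cbind(q[2, ], q[3, ])]
    e24 <- A[cbind(q[2, ], q[4, ])]; e34 <- A[cbind(q[3, ], q[4, ])]
    e <- e12 + e13 + e14 + e23 + e24 + e34
    d1 <- e12 + e13 + e14; d2 <- e12 + e23 + e24
    d3 <- e13 + e23 + e34; d4 <- e14 + e24 + e34
    maxd <- pmax(d1, d2, d3, d4)
    mind <- pmin(d1, d2, d3, d4)
    counts["G3"] <- sum(e == 3L & mind >= 1L & maxd == 2L)
    counts["G4"] <- sum(e == 3L & maxd == 3L)
    counts["G5"] <- sum(e == 4L & maxd == 2L)
    counts["G6"] <- sum(e == 4L & maxd == 3L)
    counts["G7"] <- sum(e == 5L)
    counts["G8"] <- sum(e == 6L)
  }
  counts
}

#' Incremental graphlet counting
#'
#' `graphlet_trace()` replays a sequence of single-edge additions and
#' removals through the incremental C++ counter, returning the full census
#' after every operation; `graphlet_counts()` builds a graph edge by edge
#' and returns the final census. Both agree exactly with
#' [count_graphlets()] at every step, at a per-operation cost bounded by
#' the distance-2 neighbourhood of the toggled edge rather than a global
#' re-enumeration.
#'
#' @param n_nodes number of nodes (node indices are `1..n_nodes`).
#' @param ops data frame or matrix with columns `u`, `v`, `op` where `op`
#'   is 1 for add and 0 for remove.
#' @return For `graphlet_trace()`, a numeric matrix with one row per
#'   operation and columns `G0`..`G8`; for `graphlet_counts()`, a named
#'   vector.
#' @export
graphlet_trace <- function(n_nodes, ops) {
  ops <- as.matrix(ops)
  storage.mode(ops) <- "integer"
  cpp_graphlet_trace(as.integer(n_nodes), ops)
}

#' @rdname graphlet_trace
#' @param edges two-column matrix of edges (indices in `1..n_nodes`).
#' @export
graphlet_counts <- function(n_nodes, edges) {
  edges <- as.matrix(edges)
  storage.mode(edges) <- "integer"
  cpp_graphlet_counts(as.integer(n_nodes), edges)
}

#' Relative frequency of the G4 star among 4-node graphlets
#'
#' Hub-centred modules promote 3-star (G4) graphlets, so their share of all
#' connected 4-node graphlets measures how modular and hub-like a network
#' is. Returns 0 when the graph has no connected 4-node subgraph, so tiny
#' subnetworks consistently emit the maximal "too few hubs" signal.
#'
#' @param counts named vector as returned by [count_graphlets()].
#' @return A value in `[0, 1]`.
#' @export
g4_relative_frequency <- function(counts) {
  denom <- sum(counts[paste0("G", 3:8)])
  if (denom == 0) 0 else unname(counts["G4"] / denom)
}
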