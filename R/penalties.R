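#' V-shaped structural penalty mapping
#'
#' Each structural statistic `y` of a subnetwork is turned into a cost by
#' the piecewise-linear map `|a * y + b|`. With `clamp = TRUE` the cost is
#' zero for `y` left of the intercept instead of rising again, used for
#' statistics where undershooting the target carries no meaning (the
#' anti-dominating penalty).
#'
#' @param y structural statistic value(s).
#' @param a slope.
#' @param b intercept.
#' @param clamp zero the cost where `a * y + b < 0` instead of reflecting.
#' @return Nonnegative cost value(s).
#' @export
vshape <- function(y, a, b, clamp = FALSE) {
  v <- a * y + b
  if (clamp) pmax(v, 0) else abs(v)
}

#' Define one weighted structural penalty
#'
#' The three shipped statistics are the published defaults: `"graphlet"`
#' drives subnetworks toward a high share of G4 star graphlets (zero cost
#' when all 4-node graphlets are stars), `"regulatory"` discourages
#' networks in which most genes have outgoing links, and
#' `"antidominating"` discourages a single regulator owning an excessive
#' fraction of all links (cost clamped to zero while the largest hub owns
#' at most half of a subnetwork's links, so ordinary modular hubs are
#' free).
#' Custom shapes are set through `a`, `b`, `weight`.
#'
#' @param name one of `"graphlet"`, `"regulatory"`, `"antidominating"`.
#' @param a,b v-shape slope and intercept; defaults depend on `name`.
#' @param weight nonnegative relative weight; defaults are 25 (graphlet),
#'   2 (regulatory) and 75 (anti-dominating).
#' @param clamp zero cost left of the intercept; default `TRUE` only for
#'   the anti-dominating penalty.
#' @return A list of class `netter_penalty`.
#' @export
structural_penalty <- function(name = c("graphlet", "regulatory",
                                        "antidominating"),
                               a = NULL, b = NULL, weight = NULL,
                               clamp = NULL) {
  name <- match.arg(name)
  defaults <- list(
    graphlet = list(a = 1, b = -1, weight = 25, clamp = FALSE),
    regulatory = list(a = 1, b = 0, weight = 2, clamp = FALSE),
    antidominating = list(a = 1, b = -0.5, weight = 75, clamp = TRUE))[[name]]
  p <- list(name = name,
            a = if (is.null(a)) defaults$a else a,
            b = if (is.null(b)) defaults$b else b,
            weight = if (is.null(weight)) defaults$weight else weight,
            clamp = if (is.null(clamp)) defaults$clamp else clamp)
  if (p$weight < 0) stop("penalty weight must be nonnegative")
  class(p) <- "netter_penalty"
  p
}

#' Structural cost configuration
#'
#' Bundles the penalty set, the global balance factor `alpha` weighing the
#' divergence term against the structural term, the subnetwork step size
#' `n` (prefix subnetworks are built at cut points `n, 2n, ...` strictly
#' below `x`) and the geometric subnetwork coefficients
#' `pi_i = pi_base^i`, which decay with subnetwork size so the top of the
#' ranking dominates the structural cost.
#'
#' @param penalties list of [structural_penalty()] objects.
#' @param alpha nonnegative global balance factor (default `1e-5`).
#' @param n subnetwork step size in links (default 25).
#' @param pi_base base of the geometric coefficient rule, in (0, 1)
#'   (default 0.5).
#' @return A list of class `netter_structural_config`.
#' @export
structural_config <- function(penalties = list(structural_penalty("graphlet"),
                                               structural_penalty("regulatory"),
                                               structural_penalty("antidominating")),
                              alpha = 1e-5, n = 25, pi_base = 0.5) {
  stopifnot(length(penalties) >= 1,
            all(vapply(penalties, inherits, logical(1), "netter_penalty")))
  if (alpha < 0) stop("alpha must be nonnegative")
  if (n < 1) stop("subnetwork step n must be >= 1")
  if (pi_base <= 0 || pi_base >= 1)
    stop("pi_base must lie in (0, 1) so that coefficients decrease")
  structure(list(penalties = penalties, alpha = alpha, n = as.integer(n),
                 pi_base = pi_base),
            class = "netter_structural_config")
}

pi_coefficients <- function(config, n_subnets) config$pi_base^seq_len(n_subnets)

penalty_stat_code <- function(p) {
  match(p$name, c("graphlet", "regulatory", "antidominating")) - 1L
}

#' Structural statistics of a directed subnetwork
#'
#' `regulatory_y()` is the fraction of genes present in the subnetwork that
#' have at least one outgoing link; `antidominating_y()` is the largest
#' out-degree divided by the number of links. Both are plain-R reference
#' implementations operating on an edge table; the optimizer evaluates the
#' same statistics from its incremental caches.
#'
#' @param edges data frame or matrix with regulator and target columns.
#' @return A value in `[0, 1]`; empty input yields 0.
#' @export
regulatory_y <- function(edges) {
  edges <- as.data.frame(edges)
  if (nrow(edges) == 0L) return(0)
  nodes <- unique(c(edges[[1L]], edges[[2L]]))
  length(unique(edges[[1L]])) / length(nodes)
}

#' @rdname regulatory_y
#' @export
antidominating_y <- function(edges) {
  edges <- as.data.frame(edges)
  if (nrow(edges) == 0L) return(0)
  max(table(edges[[1L]])) / nrow(edges)
}

#' Structural and total cost of a ranking (reference implementation)
#'
#' From-scratch evaluation in plain R: prefix subnetworks are materialized
#' at each cut point, the graphlet census is taken by brute-force
#' enumeration on the collapsed undirected view, and the weighted v-shaped
#' penalties are summed with the subnetwork coefficients. Quadratic in the
#' subnetwork sizes; intended for small instances and as the oracle against
#' the incrementally maintained engine cost.
#'
#' @param ranking a [new_ranking()].
#' @param config a [structural_config()].
#' @return `structural_cost_ref()`: the structural cost `s(l)`;
#'   `total_cost_ref()`: `s(l) + alpha * divergence`.
#' @export
structural_cost_ref <- function(ranking, config = structural_config()) {
  ranking <- validate_ranking(ranking)
  x <- nrow(ranking)
  cuts <- subnetwork_cuts(x, config$n)
  pis <- pi_coefficients(config, length(cuts))
  ord <- ranking[order(ranking$rank), , drop = FALSE]
  total <- 0
  for (i in seq_along(cuts)) {
    sub <- ord[seq_len(cuts[i]), , drop = FALSE]
    und <- unique(t(apply(cbind(sub$regulator, sub$target), 1L, sort)))
    ci <- 0
    for (p in config$penalties) {
      if (p$weight == 0) next
      y <- switch(p$name,
                  graphlet = g4_relative_frequency(count_graphlets(und)),
                  regulatory = regulatory_y(sub[, c("regulator", "target")]),
                  antidominating = antidominating_y(sub[, c("regulator",
                                                            "target")]))
      ci <- ci + p$weight * vshape(y, p$a, p$b, p$clamp)
    }
    total <- total + pis[i] * ci
  }
  total
}

#' @rdname structural_cost_ref
#' @export
total_cost_ref <- function(ranking, config = structural_config()) {
  structural_cost_ref(ranking, config) +
    config$alpha * divergence_cost(ranking)
}
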