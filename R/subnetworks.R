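#' Cut points of the nested prefix subnetworks
#'
#' The structural cost is evaluated on subnetworks built from ranking
#' prefixes of `n, 2n, ...` links, up to the largest multiple of `n`
#' strictly below `x` (so with `n` dividing `x` there are `x/n - 1`
#' subnetworks and the largest holds `x - n` links).
#'
#' @param x number of ranked links.
#' @param n subnetwork step size; must satisfy `1 <= n < x`.
#' @return Increasing integer vector of cut points.
#' @examples
#' subnetwork_cuts(100, 25)  # 25 50 75
#' @export
subnetwork_cuts <- function(x, n) {
  x <- as.integer(x); n <- as.integer(n)
  if (n < 1 || n >= x) stop("subnetwork step must satisfy 1 <= n < x")
  seq.int(n, x - 1L, by = n)
}

#' Build the incrementally tracked subnetwork stack for a ranking
#'
#' Materializes the C++ engine holding the current rank permutation, the
#' nested prefix subnetworks at every cut point (directed edge sets with
#' their collapsed undirected graphlet censuses and degree caches) and the
#' divergence term. Moves are applied through [apply_move()] as revertible
#' transactions; every cached statistic is updated incrementally so that a
#' proposal touches only the subnetworks whose boundary a displaced link
#' crosses.
#'
#' @param ranking a [new_ranking()].
#' @param config a [structural_config()].
#' @return An object of class `netter_stack`.
#' @export
build_subnetworks <- function(ranking, config = structural_config()) {
  ranking <- validate_ranking(ranking)
  x <- nrow(ranking)
  if (config$n >= x) stop("subnetwork step must satisfy 1 <= n < x")
  ord <- ranking[order(ranking$orig_rank), , drop = FALSE]
  genes <- sort(unique(c(ord$regulator, ord$target)))
  cuts <- subnetwork_cuts(x, config$n)
  pens <- config$penalties
  ptr <- cpp_engine_new(
    match(ord$regulator, genes) - 1L, match(ord$target, genes) - 1L,
    length(genes), config$n,
    vapply(pens, penalty_stat_code, integer(1)),
    vapply(pens, `[[`, numeric(1), "a"),
    vapply(pens, `[[`, numeric(1), "b"),
    vapply(pens, `[[`, numeric(1), "weight"),
    vapply(pens, `[[`, logical(1), "clamp"),
    pi_coefficients(config, length(cuts)), config$alpha, TRUE)
  st <- list(ptr = ptr, genes = genes, x = x, cuts = cuts, config = config,
             links = ord[, c("regulator", "target")])
  class(st) <- "netter_stack"
  # replay any pre-existing divergence of the supplied ranking
  if (!identical(ord$rank, ord$orig_rank)) {
    cpp_engine_apply(st$ptr, order(ord$rank), sort(ord$rank))
    cpp_engine_commit(st$ptr)
  }
  st
}

#' @export
print.netter_stack <- function(x, ...) {
  cat(sprintf(paste0("<netter_stack> %d links, %d genes, %d subnetworks ",
                     "(cuts %s)\n"),
              x$x, length(x$genes), length(x$cuts),
              paste(x$cuts, collapse = ", ")))
  invisible(x)
}

#' Apply and revert rank moves on a subnetwork stack
#'
#' `apply_move()` moves the given links (identified by their original
#' rank, which is the stable link id) to the given new ranks, one after the
#' other; displaced links shift by one position. All subnetwork edge sets
#' and caches are updated incrementally and the transaction is recorded so
#' that `revert_move()` restores the exact pre-move state. Reverting with
#' no outstanding transaction is an error.
#'
#' @param stack a `netter_stack` from [build_subnetworks()].
#' @param links integer link ids (original ranks).
#' @param new_ranks integer target ranks, one per link.
#' @return `stack`, invisibly.
#' @export
apply_move <- function(stack, links, new_ranks) {
  stopifnot(inherits(stack, "netter_stack"),
            length(links) == length(new_ranks))
  cpp_engine_apply(stack$ptr, as.integer(links), as.integer(new_ranks))
  invisible(stack)
}

#' @rdname apply_move
#' @export
revert_move <- function(stack) {
  stopifnot(inherits(stack, "netter_stack"))
  cpp_engine_revert(stack$ptr)
  invisible(stack)
}

#' Inspect a subnetwork stack
#'
#' `current_ranks()` returns the rank of every link (indexed by link id =
#' original rank); `subnetwork_edges()` the directed edge table of the
#' `i`-th subnetwork; `subnetwork_counts()` its graphlet census on the
#' collapsed undirected view; `subnetwork_ys()` its three structural
#' statistics; `stack_total_cost()` the incrementally maintained total
#' cost; and `stack_scratch_cost()` the same quantity recomputed from
#' scratch (the correctness oracle for the incremental caches).
#'
#' @param stack a `netter_stack`.
#' @param i subnetwork index, `1..length(stack$cuts)`.
#' @export
current_ranks <- function(stack) cpp_engine_ranks(stack$ptr)

#' @rdname current_ranks
#' @export
subnetwork_edges <- function(stack, i) {
  m <- cpp_engine_edges(stack$ptr, as.integer(i))
  data.frame(regulator = stack$genes[m[, 1L]],
             target = stack$genes[m[, 2L]], stringsAsFactors = FALSE)
}

#' @rdname current_ranks
#' @export
subnetwork_counts <- function(stack, i) {
  cpp_engine_counts(stack$ptr, as.integer(i))
}

#' @rdname current_ranks
#' @export
subnetwork_ys <- function(stack, i) cpp_engine_ys(stack$ptr, as.integer(i))

#' @rdname current_ranks
#' @export
stack_total_cost <- function(stack) cpp_engine_total(stack$ptr)

#' @rdname current_ranks
#' @export
stack_scratch_cost <- function(stack) cpp_engine_scratch_total(stack$ptr)

#' @rdname current_ranks
#' @export
stack_divergence <- function(stack) cpp_engine_divergence(stack$ptr)

#' Current ranking held by a stack
#'
#' @param stack a `netter_stack`.
#' @return A [new_ranking()] with the stack's current ranks.
#' @export
stack_ranking <- function(stack) {
  new_ranking(stack$links$regulator, stack$links$target,
              orig_rank = seq_len(stack$x), rank = current_ranks(stack))
}
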