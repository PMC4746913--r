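#' Restrict a gold standard to the links of the original top-x ranking
#'
#' Re-ranking can never introduce links, so scoring is restricted to the
#' gold edges present in the original top-x list: both the original and
#' any re-ranked list are then scored against the same positives, making
#' before/after comparisons fair. Consequently the scores depend on the
#' original prediction and are not comparable across inference methods.
#'
#' @param gold a [new_gold_standard()].
#' @param original_top_x the original extracted [new_ranking()].
#' @return The restricted `netter_gold`.
#' @export
restrict_gold <- function(gold, original_top_x) {
  original_top_x <- validate_ranking(original_top_x)
  keep <- link_keys(gold) %in% link_keys(original_top_x)
  g <- gold[keep, , drop = FALSE]
  rownames(g) <- NULL
  class(g) <- c("netter_gold", "data.frame")
  g
}

#' Score a ranking against a (restricted) gold standard
#'
#' AUROC is the probability that a uniformly drawn true link outranks a
#' uniformly drawn false one (pair counting; ties cannot occur in a strict
#' ranking). AUPR is the step-wise area under the precision-recall curve,
#' `sum_k (R_k - R_{k-1}) * P_k`, without interpolation. The gold standard
#' must be nonempty and a strict subset of the ranked links, otherwise the
#' curves are undefined.
#'
#' @param ranking a [new_ranking()].
#' @param gold a `netter_gold`, already restricted to the ranked links
#'   (see [restrict_gold()]).
#' @return A list of class `netter_eval` with elements `auroc`, `aupr`,
#'   `tp_at_k` (cumulative true positives by rank) and
#'   `restricted_gold_size`.
#' @export
score_ranking <- function(ranking, gold) {
  ranking <- validate_ranking(ranking)
  ord <- ranking[order(ranking$rank), , drop = FALSE]
  labels <- link_keys(ord) %in% link_keys(gold)
  pos <- sum(labels)
  neg <- nrow(ord) - pos
  if (pos == 0L) stop("restricted gold standard is empty: scores undefined")
  if (neg == 0L)
    stop("gold standard covers every ranked link: scores undefined")
  pr <- which(labels)                     # ranks of the true links
  discordant <- sum(pr - seq_len(pos))    # false links ranked above each true
  auroc <- 1 - discordant / (pos * neg)
  aupr <- sum(seq_len(pos) / pr) / pos
  out <- list(auroc = auroc, aupr = aupr, tp_at_k = cumsum(labels),
              restricted_gold_size = pos)
  class(out) <- "netter_eval"
  out
}

#' @export
print.netter_eval <- function(x, ...) {
  cat(sprintf("<netter_eval> AUROC %.4f, AUPR %.4f (%d true links)\n",
              x$auroc, x$aupr, x$restricted_gold_size))
  invisible(x)
}

#' Compare an original and a re-ranked list against the same gold standard
#'
#' Both rankings are scored against the gold standard restricted to the
#' original list, giving `delta_auroc`/`delta_aupr`, the per-threshold
#' difference in discovered true positives (re-ranked minus original, one
#' value per rank cutoff), and top-k overlap statistics: links shared by
#' both prefixes, true positives retained from the original prefix, and
#' true positives among the links entering the re-ranked prefix.
#'
#' @param original,reranked [new_ranking()] objects over the same links.
#' @param gold a [new_gold_standard()] (unrestricted).
#' @param overlap_k prefix size for the overlap statistics (default 75).
#' @return A list of class `netter_comparison`.
#' @export
compare_rankings <- function(original, reranked, gold, overlap_k = 75) {
  original <- validate_ranking(original)
  reranked <- validate_ranking(reranked)
  if (!setequal(link_keys(original), link_keys(reranked)))
    stop("original and re-ranked lists must contain the same links")
  g <- restrict_gold(gold, original)
  s0 <- score_ranking(original, g)
  s1 <- score_ranking(reranked, g)
  tp_diff <- s1$tp_at_k - s0$tp_at_k

  k <- min(overlap_k, nrow(original))
  top0 <- link_keys(original[order(original$rank), ][seq_len(k), ])
  top1 <- link_keys(reranked[order(reranked$rank), ][seq_len(k), ])
  gk <- link_keys(g)
  entrants <- setdiff(top1, top0)
  overlap <- list(
    k = k,
    shared = length(intersect(top0, top1)),
    tp_original = sum(top0 %in% gk),
    tp_reranked = sum(top1 %in% gk),
    tp_retained = sum(intersect(top0, top1) %in% gk),
    entrants = length(entrants),
    tp_entrants = sum(entrants %in% gk))

  out <- list(original = s0, reranked = s1,
              delta_auroc = s1$auroc - s0$auroc,
              delta_aupr = s1$aupr - s0$aupr,
              tp_diff = tp_diff, overlap = overlap)
  class(out) <- "netter_comparison"
  out
}

#' @export
print.netter_comparison <- function(x, ...) {
  cat(sprintf(paste0("<netter_comparison> AUPR %.4f -> %.4f (delta %+.4f), ",
                     "AUROC %.4f -> %.4f (delta %+.4f)\n"),
              x$original$aupr, x$reranked$aupr, x$delta_aupr,
              x$original$auroc, x$reranked$auroc, x$delta_auroc))
  ov <- x$overlap
  cat(sprintf(paste0("  top-%d overlap: %d shared, TP %d -> %d ",
                     "(%d retained, %d/%d entrants true)\n"),
              ov$k, ov$shared, ov$tp_original, ov$tp_reranked,
              ov$tp_retained, ov$tp_entrants, ov$entrants))
  invisible(x)
}
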