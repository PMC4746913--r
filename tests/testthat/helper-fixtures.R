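# Shared fixture builders and independent oracles for the test suite.

# A small ranking with arbitrary gene labels; links are L1..Lx from a pool
# of gene names wide enough to avoid accidental self-loops.
make_test_ranking <- function(x, seed = 1L) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(max(8L, ceiling(sqrt(4 * x)))))
  pairs <- candidate_links(genes)
  pick <- pairs[sample(nrow(pairs), x), ]
  new_ranking(pick$regulator, pick$target)
}

# Random edge-toggle sequence on n nodes: alternates adds and removes while
# tracking presence, so every op is legal.
make_toggle_ops <- function(n_nodes, n_ops, seed = 1L) {
  set.seed(seed)
  present <- matrix(FALSE, n_nodes, n_nodes)
  ops <- matrix(0L, n_ops, 3L)
  for (k in seq_len(n_ops)) {
    u <- sample.int(n_nodes, 1L)
    v <- sample(setdiff(seq_len(n_nodes), u), 1L)
    a <- min(u, v); b <- max(u, v)
    ops[k, ] <- c(a, b, if (present[a, b]) 0L else 1L)
    present[a, b] <- !present[a, b]
  }
  ops
}

# Replay a toggle sequence through the brute-force counter, returning the
# census after every operation (the oracle for graphlet_trace()).
brute_trace <- function(n_nodes, ops) {
  present <- matrix(FALSE, n_nodes, n_nodes)
  out <- matrix(0L, nrow(ops), 9L)
  for (k in seq_len(nrow(ops))) {
    present[ops[k, 1L], ops[k, 2L]] <- ops[k, 3L] == 1L
    out[k, ] <- count_graphlets(which(present, arr.ind = TRUE),
                                nodes = seq_len(n_nodes))
  }
  colnames(out) <- paste0("G", 0:8)
  out
}

# Pair-counting AUROC oracle: explicit loop over all (true, false) pairs.
auroc_oracle <- function(labels_by_rank) {
  pos <- which(labels_by_rank)
  neg <- which(!labels_by_rank)
  if (length(pos) == 0L || length(neg) == 0L) stop("degenerate labels")
  conc <- 0L
  for (p in pos) for (q in neg) if (p < q) conc <- conc + 1L
  conc / (length(pos) * length(neg))
}

# Step-wise AUPR oracle: walk the ranking, accumulate (dR) * precision.
aupr_oracle <- function(labels_by_rank) {
  P <- sum(labels_by_rank)
  tp <- 0L
  area <- 0
  for (k in seq_along(labels_by_rank)) {
    if (labels_by_rank[k]) {
      tp <- tp + 1L
      area <- area + (1 / P) * (tp / k)
    }
  }
  area
}

# The sequence of links by current rank: the meaningful identity check for
# two rankings (the rank column of a rank-sorted ranking is always 1..x).
link_order <- function(r) paste(r$regulator, r$target)[order(r$rank)]

# Divergence oracle: direct formula on a permutation.
divergence_oracle <- function(rank, orig_rank) {
  sum((as.numeric(rank) - as.numeric(orig_rank))^2)
}
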