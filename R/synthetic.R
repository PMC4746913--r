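#' Generate a modular, hub-containing gold-standard network
#'
#' Emulates the topology the structural penalties assume: a small set of
#' regulatory genes with a heavy-tailed (approximately scale-free)
#' out-degree distribution drives modules of co-regulated target genes,
#' every non-regulator has at least one incoming link, and no gene
#' regulates itself. Module sizes and the regulator assignment are drawn
#' with Zipf-like weights so a few hub regulators dominate.
#'
#' @param n_genes total number of genes (default 100).
#' @param n_regulators number of potential regulators (default 10% of
#'   genes, at least 2).
#' @param n_modules number of co-regulated modules (default 5).
#' @param secondary_prob probability that a target also receives a link
#'   from a secondary module regulator (default 0.3).
#' @param seed RNG seed; the same seed reproduces the network exactly.
#' @return A [new_gold_standard()] with attributes `genes` (the full gene
#'   universe) and `regulators`.
#' @export
synthetic_network <- function(n_genes = 100,
                              n_regulators = max(2L, round(n_genes / 10)),
                              n_modules = 5, secondary_prob = 0.3,
                              seed = 1L) {
  if (n_regulators >= n_genes)
    stop("n_regulators must be smaller than n_genes")
  if (n_modules < 1 || n_modules > n_genes - n_regulators)
    stop("infeasible module count for this gene universe")
  set.seed(seed)
  genes <- sprintf("G%04d", seq_len(n_genes))
  regulators <- sample(genes, n_regulators)
  targets <- setdiff(genes, regulators)

  zipf <- 1 / seq_len(n_regulators)
  module_of <- sample(seq_len(n_modules), length(targets), replace = TRUE,
                      prob = 1 / seq_len(n_modules))
  # guarantee non-empty modules where possible
  for (m in seq_len(n_modules))
    if (!any(module_of == m)) module_of[sample(length(targets), 1L)] <- m

  reg <- tgt <- character(0)
  for (m in sort(unique(module_of))) {
    mt <- targets[module_of == m]
    n_regs_m <- sample(1:3, 1L)
    regs_m <- sample(regulators, min(n_regs_m, n_regulators), prob = zipf)
    primary <- regs_m[1L]
    reg <- c(reg, rep(primary, length(mt)))
    tgt <- c(tgt, mt)
    for (r2 in regs_m[-1L]) {
      pick <- mt[runif(length(mt)) < secondary_prob]
      reg <- c(reg, rep(r2, length(pick)))
      tgt <- c(tgt, pick)
    }
    # occasional regulator cascade feeding the module's primary regulator
    if (runif(1) < 0.5 && n_regulators > 1L) {
      up <- sample(setdiff(regulators, primary), 1L, prob =
                     zipf[match(setdiff(regulators, primary), regulators)])
      reg <- c(reg, up)
      tgt <- c(tgt, primary)
    }
  }
  g <- new_gold_standard(reg, tgt)
  attr(g, "genes") <- genes
  attr(g, "regulators") <- regulators
  g
}

#' Corrupt a gold standard into a noisy prediction ranking
#'
#' Produces a scored link list with the failure modes of real inference
#' output: true links near the top with Gaussian score noise; indirect
#' false positives (links between co-regulated targets of the same
#' regulator) interleaved just below their parent true links; reversed
#' duplicates of true links right next to the forward direction; and
#' random false links padding the list up to `x` entries.
#'
#' @param gold a [new_gold_standard()], ideally from
#'   [synthetic_network()].
#' @param x length of the returned scored list.
#' @param noise_sd standard deviation of the score noise on true links
#'   (default 0.15).
#' @param indirect_fp_rate probability of injecting a link between a
#'   co-regulated target pair (default 0.3).
#' @param bidir_dup_rate probability of injecting the reversal of a true
#'   link (default 0.5).
#' @param seed RNG seed.
#' @return Data frame with columns `regulator`, `target`, `score`, sorted
#'   by decreasing score, exactly `min(x, available links)` rows.
#' @export
corrupt_to_ranking <- function(gold, x, noise_sd = 0.15,
                               indirect_fp_rate = 0.3,
                               bidir_dup_rate = 0.5, seed = 1L) {
  stopifnot(inherits(gold, "netter_gold"), x >= 1)
  set.seed(seed)
  genes <- attr(gold, "genes")
  if (is.null(genes)) genes <- unique(c(gold$regulator, gold$target))
  n_true <- nrow(gold)
  if (x < n_true)
    warning(sprintf("x = %d is smaller than the %d true links; truncating",
                    x, n_true))

  true_score <- 1 - abs(rnorm(n_true, 0, noise_sd))
  parts <- list(data.frame(regulator = gold$regulator, target = gold$target,
                           score = true_score, stringsAsFactors = FALSE))

  # indirect effects: co-regulated target pairs acquire a spurious link
  # scored just below their parent true links
  for (r in unique(gold$regulator)) {
    ti <- which(gold$regulator == r)
    if (length(ti) < 2L) next
    pairs <- utils::combn(ti, 2L)
    if (ncol(pairs) > 200L) pairs <- pairs[, sample(ncol(pairs), 200L)]
    take <- runif(ncol(pairs)) < indirect_fp_rate
    if (!any(take)) next
    pairs <- pairs[, take, drop = FALSE]
    flip <- runif(ncol(pairs)) < 0.5
    a <- ifelse(flip, pairs[2L, ], pairs[1L, ])
    b <- ifelse(flip, pairs[1L, ], pairs[2L, ])
    parts[[length(parts) + 1L]] <- data.frame(
      regulator = gold$target[a], target = gold$target[b],
      score = pmin(true_score[a], true_score[b]) - 0.02 -
        abs(rnorm(ncol(pairs), 0, noise_sd / 2)),
      stringsAsFactors = FALSE)
  }

  # near-duplicate reversed links hugging their forward parent
  rev_take <- which(runif(n_true) < bidir_dup_rate)
  if (length(rev_take) > 0L)
    parts[[length(parts) + 1L]] <- data.frame(
      regulator = gold$target[rev_take], target = gold$regulator[rev_take],
      score = true_score[rev_take] - 0.01 -
        abs(rnorm(length(rev_take), 0, noise_sd / 4)),
      stringsAsFactors = FALSE)

  pred <- do.call(rbind, parts)

  # random false links padding the tail of the list
  need <- max(0L, as.integer(ceiling(1.3 * x)) - nrow(pred))
  if (need > 0L) {
    ra <- sample(genes, 4L * need, replace = TRUE)
    rb <- sample(genes, 4L * need, replace = TRUE)
    ok <- ra != rb
    fill <- data.frame(regulator = ra[ok], target = rb[ok],
                       score = rnorm(sum(ok), 0.35, 0.12),
                       stringsAsFactors = FALSE)
    pred <- rbind(pred, fill)
  }

  pred <- pred[pred$regulator != pred$target, , drop = FALSE]
  pred$score <- pmax(pred$score, 1e-6)
  pred <- pred[order(-pred$score), , drop = FALSE]
  pred <- pred[!duplicated(link_keys(pred)), , drop = FALSE]
  pred <- utils::head(pred, as.integer(x))
  rownames(pred) <- NULL
  pred
}

#' Generate a matched gold standard and corrupted prediction
#'
#' Convenience wrapper used throughout the test fixtures and examples.
#'
#' @param n_genes number of genes.
#' @param x length of the prediction list.
#' @param seed RNG seed (drives both the network and its corruption).
#' @param ... further arguments passed to [synthetic_network()] and
#'   [corrupt_to_ranking()], split by argument name.
#' @return List with elements `gold` and `prediction`.
#' @export
simulate_fixture <- function(n_genes = 100, x = 200, seed = 1L, ...) {
  dots <- list(...)
  net_args <- dots[names(dots) %in% c("n_regulators", "n_modules",
                                      "secondary_prob")]
  cor_args <- dots[names(dots) %in% c("noise_sd", "indirect_fp_rate",
                                      "bidir_dup_rate")]
  gold <- do.call(synthetic_network,
                  c(list(n_genes = n_genes, seed = seed), net_args))
  pred <- do.call(corrupt_to_ranking,
                  c(list(gold = gold, x = x, seed = seed + 1L), cor_args))
  list(gold = gold, prediction = pred)
}
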