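#' Derive per-run seeds from a master seed
#'
#' A fixed multiplicative-congruential hash keeps every run's RNG stream
#' independent of scheduling and reproducible from the master seed alone.
#'
#' @param master_seed integer master seed.
#' @param runs number of runs.
#' @return Integer vector of `runs` seeds, each in `[1, 2^31 - 2]`.
#' @export
derive_run_seeds <- function(master_seed, runs) {
  m <- 2147483647
  s <- (48271 * (as.numeric(master_seed) %% m) + seq_len(runs)) %% m
  as.integer(ifelse(s == 0, 1, s))
}

#' Average rankings rank-wise
#'
#' Every run must rank the same link set; each link receives the mean of
#' its ranks across runs and the final ranking sorts by that mean, ties
#' broken in favour of the lower original rank (conservative toward the
#' input prediction).
#'
#' @param runs list of [new_ranking()] objects over identical link sets.
#' @return The aggregated [new_ranking()].
#' @export
average_rankings <- function(runs) {
  stopifnot(is.list(runs), length(runs) >= 1)
  base <- validate_ranking(runs[[1]])
  base <- base[order(base$orig_rank), , drop = FALSE]
  key0 <- link_keys(base)
  mean_rank <- numeric(nrow(base))
  for (r in runs) {
    r <- validate_ranking(r)
    idx <- match(key0, link_keys(r))
    if (anyNA(idx) || nrow(r) != nrow(base))
      stop("all runs must rank the same link set")
    if (!identical(r$orig_rank[idx], base$orig_rank))
      stop("all runs must share the same original ranks")
    mean_rank <- mean_rank + r$rank[idx]
  }
  mean_rank <- mean_rank / length(runs)
  new_rank <- order(order(mean_rank, base$orig_rank))
  new_ranking(base$regulator, base$target,
              orig_rank = base$orig_rank, rank = new_rank)
}

#' Full re-ranking pipeline: extract, optimize, aggregate
#'
#' Extracts the top `x` links of a prediction, runs `runs` independent
#' simulated-annealing optimizations with seeds derived from the master
#' seed (so worker scheduling cannot affect the result) and aggregates
#' them rank-wise. Averaging over many runs is what makes the output
#' robust: the cost surface is non-convex with many near-optimal
#' permutations, and the rank-wise mean of independent solutions both
#' stabilizes the result and concentrates true structure at the top.
#'
#' @param pred prediction data frame (`regulator`, `target`, `score`) or a
#'   path readable by [read_prediction()].
#' @param x top-x cutoff (default 750).
#' @param config a [structural_config()].
#' @param anneal an [anneal_config()].
#' @param runs number of independent optimization runs (default 100).
#' @param seed master seed.
#' @param workers parallelism degree (forked processes via
#'   [parallel::mclapply()]; results are identical for any value).
#' @return A list of class `netter_result` with elements `ranking` (the
#'   final aggregated [new_ranking()]), `initial` (the extracted top-x
#'   ranking), `runs` (per-run re-ranked rankings) and `diagnostics`
#'   (per-run calibration summaries).
#' @export
netter_rerank <- function(pred, x = 750, config = structural_config(),
                          anneal = anneal_config(), runs = 100, seed = 1L,
                          workers = 1L) {
  if (is.character(pred)) pred <- read_prediction(pred)
  if (runs < 1) stop("runs must be >= 1")
  initial <- extract_top_x(pred, x)
  seeds <- derive_run_seeds(seed, runs)
  one <- function(i) run_annealing(initial, config, anneal, seed = seeds[i])
  results <- if (workers > 1L) {
    parallel::mclapply(seq_len(runs), one, mc.cores = workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(seq_len(runs), one)
  }
  errs <- vapply(results, inherits, logical(1), "try-error")
  if (any(errs)) stop("annealing run failed: ", results[[which(errs)[1]]])
  final <- average_rankings(lapply(results, `[[`, "ranking"))
  diag <- data.frame(
    run = seq_len(runs), seed = seeds,
    bad_accept_ratio = vapply(results, function(r)
      as.numeric(r$bad_accept_ratio), numeric(1)),
    restarts = vapply(results, function(r)
      as.integer(r$restarts), integer(1)),
    T0 = vapply(results, function(r) as.numeric(r$T0), numeric(1)))
  out <- list(ranking = final, initial = initial,
              runs = lapply(results, `[[`, "ranking"), diagnostics = diag)
  class(out) <- "netter_result"
  out
}

#' @export
print.netter_result <- function(x, ...) {
  cat(sprintf(paste0("<netter_result> %d links re-ranked over %d runs; ",
                     "final divergence %g\n"),
              nrow(x$ranking), length(x$runs), divergence_cost(x$ranking)))
  invisible(x)
}
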