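#' Simulated-annealing schedule configuration
#'
#' A mutation draws `gamma ~ Uniform{1..Gamma}` distinct links and moves
#' each by a nonzero offset `theta ~ Uniform{-Theta..Theta}` (clamped to
#' the ranking bounds). A proposal is accepted when it lowers the total
#' cost, or with probability `exp(-delta/T)` otherwise; `T` decays by the
#' factor `mu` every iteration. If the acceptance ratio of cost-increasing
#' moves over the starting window is outside `accept_band`, the run
#' restarts with `T0` doubled (ratio too low) or halved (too high), up to
#' `max_restarts` times, so `T0` and `mu` need no manual tuning. The
#' default schedule runs 30,000 iterations with a 10% window targeting
#' roughly 10% bad-move acceptance, moves at most 50 links per step by at
#' most 70 positions, and decays the temperature by four orders of
#' magnitude over the schedule.
#'
#' @param iterations total annealing steps (default 30000).
#' @param Gamma maximum number of links moved per step (default 50).
#' @param Theta maximum positional displacement per link (default 70).
#' @param start_window_fraction fraction of iterations forming the
#'   calibration window (default 0.1).
#' @param accept_band admissible bad-move acceptance ratio over the window
#'   (default `c(0.05, 0.15)`).
#' @param mu exponential cooling factor per iteration, in (0, 1).
#' @param T0 initial temperature; `NA` (default) probes 100 trial moves
#'   and sets `T0` so the mean bad move starts near the target ratio.
#' @param max_restarts calibration retry cap (default 40; a failed attempt
#'   costs only the calibration window, and 40 doublings or halvings of
#'   `T0` cover any realistically mis-set starting temperature).
#' @param accept_all accept every proposal regardless of cost (the shuffle
#'   control); disables cost tracking and calibration.
#' @param check_every if positive, verify the cached total cost against a
#'   from-scratch recomputation every that many iterations (debug oracle).
#' @param log_every if positive, record a trajectory row (iteration,
#'   temperature, total cost, structural cost, divergence, accept flag,
#'   per-penalty costs) every that many iterations.
#' @return A list of class `netter_anneal_config`.
#' @export
anneal_config <- function(iterations = 30000, Gamma = 50, Theta = 70,
                          start_window_fraction = 0.1,
                          accept_band = c(0.05, 0.15),
                          mu = 10^(-4 / iterations), T0 = NA_real_,
                          max_restarts = 40, accept_all = FALSE,
                          check_every = 0, log_every = 0) {
  stopifnot(iterations >= 1, Gamma >= 1, Theta >= 1,
            start_window_fraction > 0, start_window_fraction < 1,
            length(accept_band) == 2, accept_band[1] < accept_band[2],
            mu > 0, mu < 1, max_restarts >= 0)
  structure(list(iterations = as.integer(iterations),
                 Gamma = as.integer(Gamma), Theta = as.integer(Theta),
                 start_window_fraction = start_window_fraction,
                 accept_band = accept_band, mu = mu, T0 = T0,
                 max_restarts = as.integer(max_restarts),
                 accept_all = isTRUE(accept_all),
                 check_every = as.integer(check_every),
                 log_every = as.integer(log_every)),
            class = "netter_anneal_config")
}

#' Run one simulated-annealing re-ranking
#'
#' Minimizes `f(l) = s(l) + alpha * Delta(l)` over rank permutations of
#' the supplied top-x ranking, starting from the original order. The
#' output is bit-reproducible for a fixed seed.
#'
#' @param ranking a [new_ranking()] (typically from [extract_top_x()]).
#' @param config a [structural_config()].
#' @param anneal an [anneal_config()].
#' @param seed integer RNG seed for this run.
#' @return A list of class `netter_anneal_run` with elements `ranking`
#'   (the re-ranked [new_ranking()]), `bad_accept_ratio`, `restarts`,
#'   `T0`, `accepted`, `max_cost_err` and optionally `trajectory`.
#' @export
run_annealing <- function(ranking, config = structural_config(),
                          anneal = anneal_config(), seed = 1L) {
  ranking <- validate_ranking(ranking)
  stopifnot(inherits(config, "netter_structural_config"),
            inherits(anneal, "netter_anneal_config"))
  if (nrow(ranking) < 2L) stop("ranking must contain at least 2 links")
  ord <- ranking[order(ranking$orig_rank), , drop = FALSE]
  genes <- sort(unique(c(ord$regulator, ord$target)))
  cuts <- subnetwork_cuts(nrow(ord), config$n)
  pens <- config$penalties
  res <- cpp_anneal(
    match(ord$regulator, genes) - 1L, match(ord$target, genes) - 1L,
    length(genes), config$n,
    vapply(pens, penalty_stat_code, integer(1)),
    vapply(pens, `[[`, numeric(1), "a"),
    vapply(pens, `[[`, numeric(1), "b"),
    vapply(pens, `[[`, numeric(1), "weight"),
    vapply(pens, `[[`, logical(1), "clamp"),
    pi_coefficients(config, length(cuts)), config$alpha,
    anneal$iterations, anneal$Gamma, anneal$Theta,
    as.numeric(anneal$T0), anneal$mu, anneal$start_window_fraction,
    anneal$accept_band[1], anneal$accept_band[2], anneal$max_restarts,
    as.numeric(seed), anneal$accept_all, anneal$check_every,
    anneal$log_every)
  out <- list(
    ranking = new_ranking(ord$regulator, ord$target,
                          orig_rank = seq_len(nrow(ord)), rank = res$rank),
    bad_accept_ratio = res$bad_accept_ratio,
    restarts = res$restarts, T0 = res$T0, accepted = res$accepted,
    bad_proposed = res$bad_proposed, bad_accepted = res$bad_accepted,
    max_cost_err = res$max_cost_err, seed = seed)
  if (!is.null(res$trajectory)) out$trajectory <- res$trajectory
  class(out) <- "netter_anneal_run"
  out
}

#' @export
print.netter_anneal_run <- function(x, ...) {
  cat(sprintf(paste0("<netter_anneal_run> %d links, divergence %g, ",
                     "bad-accept ratio %.3f, %d restart(s)\n"),
              nrow(x$ranking), divergence_cost(x$ranking),
              if (is.na(x$bad_accept_ratio)) NA_real_ else
                x$bad_accept_ratio, x$restarts))
  invisible(x)
}
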