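#' Read a re-ranking configuration file
#'
#' YAML with optional keys `x`, `runs`, `alpha`, `subnetwork_size` (the
#' step `n`; the bare key `n` is also accepted but must be quoted, since
#' YAML 1.1 reads an unquoted `n` as a boolean), `pi_base`, `iterations`,
#' `Gamma`, `Theta`, and a `penalties` list of `{name, a, b, weight,
#' clamp}` entries. Missing keys fall back to the package defaults, so a
#' config file only needs to state what it changes.
#'
#' @param path path to a YAML file.
#' @return A list with elements `x`, `runs`, `structural`
#'   (a [structural_config()]) and `anneal` (an [anneal_config()]).
#' @export
read_netter_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()

  penalties <- if (is.null(cfg$penalties)) {
    list(structural_penalty("graphlet"), structural_penalty("regulatory"),
         structural_penalty("antidominating"))
  } else {
    lapply(cfg$penalties, function(p)
      structural_penalty(name = p$name, a = p$a, b = p$b,
                         weight = p$weight, clamp = p$clamp))
  }
  s_args <- list(penalties = penalties)
  for (k in c("alpha", "pi_base"))
    if (!is.null(cfg[[k]])) s_args[[k]] <- cfg[[k]]
  if (!is.null(cfg[["subnetwork_size"]])) s_args$n <- cfg[["subnetwork_size"]]
  if (!is.null(cfg[["n"]])) s_args$n <- cfg[["n"]]
  a_args <- list()
  for (k in c("iterations", "Gamma", "Theta", "start_window_fraction",
              "accept_band", "mu", "T0", "max_restarts"))
    if (!is.null(cfg[[k]])) a_args[[k]] <- cfg[[k]]

  list(x = if (is.null(cfg$x)) 750L else as.integer(cfg$x),
       runs = if (is.null(cfg$runs)) 100L else as.integer(cfg$runs),
       structural = do.call(structural_config, s_args),
       anneal = do.call(anneal_config, a_args))
}
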