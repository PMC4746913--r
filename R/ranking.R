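#' Construct a link ranking
#'
#' A ranking is an ordered list of distinct directed regulator-target links.
#' `rank` gives the current (possibly re-ranked) 1-based position of each
#' link and `orig_rank` its position in the source prediction; both are
#' permutations of `1..x`. Re-ranking never adds or removes links, so the
#' link set is fixed at construction.
#'
#' @param regulator,target character vectors of gene identifiers.
#' @param orig_rank integer positions in the source prediction
#'   (default: input order).
#' @param rank integer current positions (default: `orig_rank`).
#' @return A data frame of class `netter_ranking` with columns `regulator`,
#'   `target`, `rank`, `orig_rank`, ordered by `rank`.
#' @examples
#' r <- new_ranking(c("A", "A", "B"), c("B", "C", "C"))
#' divergence_cost(r)
#' @export
new_ranking <- function(regulator, target,
                        orig_rank = seq_along(regulator),
                        rank = orig_rank) {
  r <- data.frame(regulator = as.character(regulator),
                  target = as.character(target),
                  rank = as.integer(rank),
                  orig_rank = as.integer(orig_rank),
                  stringsAsFactors = FALSE)
  r <- r[order(r$rank), , drop = FALSE]
  rownames(r) <- NULL
  class(r) <- c("netter_ranking", "data.frame")
  validate_ranking(r)
}

#' @rdname new_ranking
#' @param r object to validate.
#' @export
validate_ranking <- function(r) {
  stopifnot(is.data.frame(r),
            all(c("regulator", "target", "rank", "orig_rank") %in% names(r)))
  x <- nrow(r)
  if (x == 0L) stop("a ranking must contain at least one link")
  if (any(r$regulator == r$target))
    stop("self-loops are not allowed in a ranking")
  key <- paste(r$regulator, r$target, sep = "\r")
  if (anyDuplicated(key)) stop("ranking links must be distinct")
  if (!identical(sort(r$rank), seq_len(x)))
    stop("ranks must be exactly 1..x with no gaps")
  if (!identical(sort(r$orig_rank), seq_len(x)))
    stop("original ranks must be exactly 1..x with no gaps")
  r
}

link_keys <- function(df) paste(df$regulator, df$target, sep = "\r")

#' @export
print.netter_ranking <- function(x, ...) {
  cat(sprintf("<netter_ranking> %d links, %d genes, divergence %g\n",
              nrow(x), length(unique(c(x$regulator, x$target))),
              divergence_cost(x)))
  print(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}

#' Read a prediction file in DREAM edge-list format
#'
#' Parses a 3-column TSV (`regulator`, `target`, `confidence`), the usual
#' output dialect of network inference methods. A header line is detected by
#' a non-numeric third field. Rows are returned sorted by strictly
#' decreasing score with ties broken by file order; self-loops are dropped
#' with a warning and duplicated ordered pairs keep the higher-scored
#' occurrence.
#'
#' @param path path to the TSV file.
#' @param fmt input dialect; only `"dream_tsv"` is supported.
#' @return A data frame with columns `regulator`, `target`, `score`.
#' @export
read_prediction <- function(path, fmt = "dream_tsv") {
  fmt <- match.arg(fmt, "dream_tsv")
  if (!file.exists(path)) stop("prediction file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("prediction file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  first_line <- 1L
  if (length(fields[[1]]) >= 3L &&
      is.na(suppressWarnings(as.numeric(fields[[1]][3L]))))
    first_line <- 2L  # header
  if (first_line > length(fields)) stop("prediction file is empty: ", path)
  n <- length(fields)
  reg <- tgt <- character(n)
  score <- numeric(n)
  keep <- logical(n)
  for (i in seq.int(first_line, n)) {
    f <- fields[[i]]
    if (length(f) < 3L)
      stop(sprintf("malformed prediction row at line %d: expected 3 fields",
                   i))
    s <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(s))
      stop(sprintf("malformed prediction row at line %d: non-numeric score",
                   i))
    reg[i] <- f[1L]; tgt[i] <- f[2L]; score[i] <- s; keep[i] <- TRUE
  }
  df <- data.frame(regulator = reg[keep], target = tgt[keep],
                   score = score[keep], stringsAsFactors = FALSE)
  loops <- df$regulator == df$target
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop row(s) from %s", sum(loops), path))
    df <- df[!loops, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("prediction contains no usable links: ", path)
  df <- df[order(-df$score, seq_len(nrow(df))), , drop = FALSE]
  df <- df[!duplicated(link_keys(df)), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Extract the top-x links of a prediction as a ranking
#'
#' The re-ranking works on the `x` most confident links only; links beyond
#' position `x` keep their original ranks and never enter the optimization.
#' Links with a zero score carry no confidence and are not extracted, so
#' fewer than `x` links may be returned.
#'
#' @param pred data frame with columns `regulator`, `target`, `score`,
#'   sorted by decreasing score (as returned by [read_prediction()]).
#' @param x number of top links to extract.
#' @return A [new_ranking()] of `min(x, #nonzero-score links)` links.
#' @export
extract_top_x <- function(pred, x) {
  if (!is.numeric(x) || length(x) != 1L || x < 1)
    stop("x must be a positive integer")
  stopifnot(all(c("regulator", "target", "score") %in% names(pred)))
  pred <- pred[pred$score != 0, , drop = FALSE]
  if (nrow(pred) == 0L) stop("prediction has no links with nonzero score")
  top <- utils::head(pred, as.integer(x))
  new_ranking(top$regulator, top$target)
}

#' Divergence of a ranking from its source prediction
#'
#' The sum over links of the squared displacement between current and
#' original rank. This is the regularization term that anchors a re-ranked
#' list to the prediction it came from; it is zero exactly when the
#' permutation is the identity.
#'
#' @param r a [new_ranking()].
#' @return Nonnegative number.
#' @export
divergence_cost <- function(r) {
  r <- validate_ranking(r)
  sum((as.numeric(r$rank) - as.numeric(r$orig_rank))^2)
}

#' Write a ranking to a TSV file
#'
#' Rows are `regulator`, `target`, `rank` in ascending rank order, with a
#' header. [read_ranking()] round-trips the order exactly.
#'
#' @param r a [new_ranking()].
#' @param path output path.
#' @export
write_ranking <- function(r, path) {
  r <- validate_ranking(r)
  out <- data.frame(regulator = r$regulator, target = r$target,
                    rank = r$rank)
  out <- out[order(out$rank), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_ranking
#' @export
read_ranking <- function(path) {
  if (!file.exists(path)) stop("ranking file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "integer"))
  new_ranking(df$regulator, df$target, orig_rank = df$rank)
}

#' Enumerate all candidate directed links over a gene set
#'
#' All ordered gene pairs excluding self-loops: `G * (G - 1)` links for `G`
#' genes (9,900 for a 100-gene network) -- the size of a complete ranking.
#'
#' @param genes character vector of gene identifiers.
#' @return Data frame with columns `regulator`, `target`.
#' @export
candidate_links <- function(genes) {
  genes <- unique(as.character(genes))
  g <- expand.grid(target = genes, regulator = genes,
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  g <- g[g$regulator != g$target, c("regulator", "target")]
  rownames(g) <- NULL
  g
}

#' Gold-standard edge sets
#'
#' A gold standard is the set of true directed regulatory links used for
#' evaluation. `read_gold_standard()` accepts either a 2-column TSV of true
#' edges or the 3-column DREAM dialect (`regulator`, `target`, `{0,1}`)
#' where only rows flagged 1 are kept.
#'
#' @param regulator,target character vectors of gene identifiers.
#' @return A data frame of class `netter_gold` with columns `regulator`
#'   and `target`.
#' @export
new_gold_standard <- function(regulator, target) {
  g <- data.frame(regulator = as.character(regulator),
                  target = as.character(target), stringsAsFactors = FALSE)
  if (any(g$regulator == g$target))
    stop("self-loops are not allowed in a gold standard")
  g <- g[!duplicated(link_keys(g)), , drop = FALSE]
  rownames(g) <- NULL
  class(g) <- c("netter_gold", "data.frame")
  g
}

#' @rdname new_gold_standard
#' @param path path to a gold-standard TSV file.
#' @export
read_gold_standard <- function(path) {
  if (!file.exists(path)) stop("gold-standard file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) >= 3L) df <- df[df[[3L]] == 1, , drop = FALSE]
  new_gold_standard(df[[1L]], df[[2L]])
}
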