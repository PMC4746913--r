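test_that("prediction files are parsed, sorted and deduplicated", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB\t0.9", "B\tC\t0.5", "A\tC\t0.7"), path)
  p <- read_prediction(path)
  expect_equal(p$regulator, c("A", "A", "B"))
  expect_equal(p$target, c("B", "C", "C"))
  expect_equal(p$score, c(0.9, 0.7, 0.5))

  # header detection by non-numeric third field
  writeLines(c("from\tto\tconfidence", "A\tB\t0.9", "B\tC\t0.5"), path)
  expect_equal(nrow(read_prediction(path)), 2L)

  # self-loops dropped with a warning
  writeLines(c("A\tA\t0.99", "A\tB\t0.5"), path)
  expect_warning(p <- read_prediction(path), "self-loop")
  expect_equal(nrow(p), 1L)

  # duplicate ordered pairs keep the higher score
  writeLines(c("A\tB\t0.9", "C\tD\t0.5", "A\tB\t0.3"), path)
  p <- read_prediction(path)
  expect_equal(nrow(p), 2L)
  expect_equal(p$score[p$regulator == "A"], 0.9)

  # score ties broken by file order
  writeLines(c("A\tB\t0.5", "B\tC\t0.5", "A\tC\t0.5"), path)
  p <- read_prediction(path)
  expect_equal(paste(p$regulator, p$target), c("A B", "B C", "A C"))
})

test_that("malformed and empty prediction files are rejected with context", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB\t0.9", "B\tC"), path)
  expect_error(read_prediction(path), "line 2")
  writeLines(c("A\tB\t0.9", "B\tC\tnotanumber"), path)
  expect_error(read_prediction(path), "line 2")
  writeLines(character(0), path)
  expect_error(read_prediction(path), "empty")
  expect_error(read_prediction(file.path(tempdir(), "nope.tsv")),
               "not found")
})

test_that("top-x extraction freezes links beyond x and drops zero scores", {
  genes <- sprintf("G%03d", 1:100)
  all_links <- candidate_links(genes)
  pred <- data.frame(all_links, score = rev(seq_len(nrow(all_links))))
  expect_equal(nrow(pred), 9900L)
  r <- extract_top_x(pred, 750)
  expect_s3_class(r, "netter_ranking")
  expect_equal(nrow(r), 750L)
  expect_equal(r$orig_rank, 1:750)
  # the extracted links are exactly the 750 best-scored ones
  expect_equal(paste(r$regulator, r$target),
               paste(pred$regulator, pred$target)[1:750])

  # fewer nonzero-score links than x
  pred$score[401:9900] <- 0
  expect_equal(nrow(extract_top_x(pred, 750)), 400L)

  # x equal to the prediction size is the identity
  small <- pred[1:5, ]
  r5 <- extract_top_x(small, 5)
  expect_equal(paste(r5$regulator, r5$target),
               paste(small$regulator, small$target))

  expect_error(extract_top_x(pred, 0), "positive")
})

test_that("divergence cost matches the squared-displacement formula", {
  r <- make_test_ranking(10)
  expect_equal(divergence_cost(r), 0)

  # swapping ranks 1 and 2 costs 1^2 + 1^2
  r2 <- new_ranking(r$regulator, r$target, orig_rank = r$orig_rank,
                    rank = c(2L, 1L, 3:10))
  expect_equal(divergence_cost(r2), 2)

  # moving rank 1 to rank 4 shifts three links up by one: 9 + 1 + 1 + 1
  r3 <- new_ranking(r$regulator, r$target, orig_rank = r$orig_rank,
                    rank = c(4L, 1L, 2L, 3L, 5:10))
  expect_equal(divergence_cost(r3), 12)

  # single-link move by d positions costs d^2 + d, checked against the
  # direct oracle for every legal displacement
  for (d in 1:9) {
    rank <- seq_len(10L)
    rank[1L] <- 1L + d
    rank[2:(1 + d)] <- 1:d
    rd <- new_ranking(r$regulator, r$target, orig_rank = r$orig_rank,
                      rank = rank)
    expect_equal(divergence_cost(rd), d^2 + d)
    expect_equal(divergence_cost(rd), divergence_oracle(rank, 1:10))
  }
})

test_that("divergence is invariant under gene relabeling", {
  r <- make_test_ranking(25, seed = 7)
  set.seed(3)
  perm <- sample(nrow(r))
  rp <- new_ranking(r$regulator, r$target, orig_rank = r$orig_rank,
                    rank = perm)
  relabel <- setNames(sprintf("X%03d", seq_along(unique(c(r$regulator,
                                                          r$target)))),
                      unique(c(r$regulator, r$target)))
  rq <- new_ranking(relabel[rp$regulator], relabel[rp$target],
                    orig_rank = rp$orig_rank, rank = rp$rank)
  expect_equal(divergence_cost(rq), divergence_cost(rp))
})

test_that("ranking invariants are enforced", {
  expect_error(new_ranking("A", "A"), "self-loop")
  expect_error(new_ranking(c("A", "A"), c("B", "B")), "distinct")
  expect_error(new_ranking(c("A", "B"), c("B", "C"), rank = c(1L, 3L)),
               "1..x")
  expect_error(new_ranking(character(0), character(0)), "at least one")
})

test_that("write/read round-trips a ranking bit-exactly", {
  r <- make_test_ranking(20, seed = 5)
  set.seed(9)
  r <- new_ranking(r$regulator, r$target, orig_rank = r$orig_rank,
                   rank = sample(20L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ranking(r, path)
  r2 <- read_ranking(path)
  ord1 <- r[order(r$rank), c("regulator", "target")]
  ord2 <- r2[order(r2$rank), c("regulator", "target")]
  expect_equal(ord1$regulator, ord2$regulator)
  expect_equal(ord1$target, ord2$target)
  expect_error(write_ranking(data.frame(), path))
})

test_that("gold standards reject self-loops and read both TSV dialects", {
  expect_error(new_gold_standard("A", "A"), "self-loop")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB\t1", "A\tC\t0", "B\tC\t1"), path)
  g <- read_gold_standard(path)
  expect_equal(nrow(g), 2L)
  writeLines(c("A\tB", "B\tC"), path)
  expect_equal(nrow(read_gold_standard(path)), 2L)
})
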