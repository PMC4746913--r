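test_that("brute-force census classifies the canonical small graphs", {
  k4 <- t(utils::combn(4, 2))
  c_k4 <- count_graphlets(k4)
  expect_equal(unname(c_k4[c("G8", "G7", "G2", "G1")]), c(1L, 0L, 4L, 0L))

  claw <- rbind(c(1, 2), c(1, 3), c(1, 4))
  c_claw <- count_graphlets(claw)
  expect_equal(unname(c_claw[c("G4", "G1", "G2", "G3")]), c(1L, 3L, 0L, 0L))

  c5 <- cbind(1:5, c(2:5, 1))
  c_c5 <- count_graphlets(c5)
  expect_equal(unname(c_c5["G3"]), 5L)
  expect_equal(sum(c_c5[paste0("G", 4:8)]), 0L)

  # G0 tracks edges; 4-node classes sum to the connected quadruple count
  path4 <- rbind(c(1, 2), c(2, 3), c(3, 4))
  expect_equal(unname(count_graphlets(path4)["G3"]), 1L)
  expect_equal(unname(count_graphlets(path4)["G0"]), 3L)
})

test_that("incremental single-edge updates match the published examples", {
  # empty graph + edge
  tr <- graphlet_trace(4, rbind(c(1L, 2L, 1L)))
  expect_equal(unname(tr[1, ]), c(1, rep(0, 8)))

  # path a-b-c, add c-d: two 2-paths and one 4-path
  tr <- graphlet_trace(4, rbind(c(1L, 2L, 1L), c(2L, 3L, 1L),
                                c(3L, 4L, 1L)))
  expect_equal(unname(tr[3, c("G1", "G3")]), c(2, 1))

  # diamond minus one chord (4-cycle), add the chord: G5 -1, G7 +1
  cyc <- rbind(c(1L, 2L, 1L), c(2L, 3L, 1L), c(3L, 4L, 1L), c(4L, 1L, 1L))
  tr <- graphlet_trace(4, rbind(cyc, c(1L, 3L, 1L)))
  expect_equal(unname(tr[4, c("G5", "G7")]), c(1, 0))
  expect_equal(unname(tr[5, c("G5", "G7")]), c(0, 1))

  # K4 remove one edge leaves a diamond
  k4 <- cbind(t(utils::combn(4L, 2L)), 1L)
  tr <- graphlet_trace(4, rbind(k4, c(1L, 2L, 0L)))
  expect_equal(unname(tr[6, c("G8", "G7")]), c(1, 0))
  expect_equal(unname(tr[7, c("G8", "G7")]), c(0, 1))
})

test_that("add then remove restores counts exactly", {
  # ops only touch nodes 1..9, so edge (9, 10) is guaranteed absent
  ops <- make_toggle_ops(9, 60, seed = 21)
  last <- graphlet_trace(10, ops)[60, ]
  tr2 <- graphlet_trace(10, rbind(ops, c(9L, 10L, 1L), c(9L, 10L, 0L)))
  expect_equal(unname(tr2[nrow(tr2), ]), unname(last))
})

test_that("illegal edge operations are rejected", {
  expect_error(graphlet_trace(4, rbind(c(1L, 2L, 1L), c(2L, 1L, 1L))),
               "already present")
  expect_error(graphlet_trace(4, rbind(c(1L, 2L, 0L))), "not present")
  expect_error(graphlet_trace(4, rbind(c(1L, 1L, 1L))), "self-loop")
})

test_that("incremental counts equal brute force on random toggle sequences", {
  for (s in 1:6) {
    n <- sample(6:12, 1)
    ops <- make_toggle_ops(n, 80, seed = 100 + s)
    expect_equal(unname(graphlet_trace(n, ops)), unname(brute_trace(n, ops)),
                 info = sprintf("seed %d", s))
  }
})

test_that("counting is invariant under node relabeling", {
  ops <- make_toggle_ops(9, 50, seed = 77)
  set.seed(78)
  perm <- sample(9L)
  ops2 <- ops
  ops2[, 1:2] <- matrix(perm[ops[, 1:2]], ncol = 2)
  # normalize u < v not required by the counter; feed as-is
  expect_equal(graphlet_trace(9, ops)[50, ], graphlet_trace(9, ops2)[50, ])
})

test_that("brute-force census agrees with igraph isomorphism-class counts", {
  set.seed(5)
  n <- 9
  ops <- make_toggle_ops(n, 40, seed = 5)
  # final graph of the toggle sequence
  present <- matrix(FALSE, n, n)
  for (k in seq_len(nrow(ops)))
    present[ops[k, 1], ops[k, 2]] <- ops[k, 3] == 1L
  edges <- which(present, arr.ind = TRUE)
  ours <- count_graphlets(edges, nodes = seq_len(n))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, n - igraph::vcount(g))
  m3 <- igraph::motifs(g, 3)
  m4 <- igraph::motifs(g, 4)
  # locate each connected class through its representative's isoclass id
  rep_graph <- function(el) igraph::graph_from_edgelist(el, directed = FALSE)
  iso3 <- function(el) igraph::graph.isoclass(rep_graph(el)) + 1L
  iso4 <- function(el) igraph::graph.isoclass(rep_graph(el)) + 1L
  expect_equal(unname(ours["G1"]), m3[iso3(rbind(c(1, 2), c(2, 3)))])
  expect_equal(unname(ours["G2"]),
               m3[iso3(rbind(c(1, 2), c(2, 3), c(1, 3)))])
  expect_equal(unname(ours["G3"]),
               m4[iso4(rbind(c(1, 2), c(2, 3), c(3, 4)))])
  expect_equal(unname(ours["G4"]),
               m4[iso4(rbind(c(1, 2), c(1, 3), c(1, 4)))])
  expect_equal(unname(ours["G5"]),
               m4[iso4(rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1)))])
  expect_equal(unname(ours["G6"]),
               m4[iso4(rbind(c(1, 2), c(2, 3), c(1, 3), c(3, 4)))])
  expect_equal(unname(ours["G7"]),
               m4[iso4(rbind(c(1, 2), c(2, 3), c(1, 3), c(3, 4), c(1, 4)))])
  expect_equal(unname(ours["G8"]), m4[iso4(t(utils::combn(4, 2)))])
})

test_that("G4 relative frequency follows its definition and conventions", {
  claw <- count_graphlets(rbind(c(1, 2), c(1, 3), c(1, 4)))
  expect_equal(g4_relative_frequency(claw), 1)
  path4 <- count_graphlets(rbind(c(1, 2), c(2, 3), c(3, 4)))
  expect_equal(g4_relative_frequency(path4), 0)
  fake <- setNames(c(0, 0, 0, 3, 1, 0, 0, 0, 0), paste0("G", 0:8))
  expect_equal(g4_relative_frequency(fake), 0.25)
  empty <- count_graphlets(matrix(numeric(0), 0, 2), nodes = 1:3)
  expect_equal(g4_relative_frequency(empty), 0)
})
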