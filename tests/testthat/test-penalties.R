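test_that("the v-shaped mapping reflects or clamps around its intercept", {
  expect_equal(vshape(1, a = 1, b = -1), 0)
  expect_equal(vshape(0.25, a = 1, b = -1), 0.75)
  expect_equal(vshape(0, a = -2, b = 1), 1)
  # clamped variant zeroes the left branch only
  expect_equal(vshape(0.2, a = 1, b = -0.5, clamp = TRUE), 0)
  expect_equal(vshape(0.8, a = 1, b = -0.5, clamp = TRUE),
               vshape(0.8, a = 1, b = -0.5))
})

test_that("regulatory statistic is the regulator fraction of present genes", {
  expect_equal(regulatory_y(data.frame(r = c("A", "A", "B"),
                                       t = c("B", "C", "C"))), 2 / 3)
  expect_equal(regulatory_y(data.frame(r = c("A", "A", "A"),
                                       t = c("B", "C", "D"))), 0.25)
  tri <- data.frame(r = c("A", "B", "B", "C", "C", "A"),
                    t = c("B", "A", "C", "B", "A", "C"))
  expect_equal(regulatory_y(tri), 1)
  expect_equal(regulatory_y(data.frame(r = character(0), t = character(0))),
               0)
})

test_that("anti-dominating statistic is the top hub's link share", {
  expect_equal(antidominating_y(data.frame(r = c("A", "A", "A", "B"),
                                           t = c("B", "C", "D", "C"))),
               0.75)
  expect_equal(antidominating_y(data.frame(r = c("A", "B", "C", "D"),
                                           t = c("E", "F", "G", "H"))),
               0.25)
  expect_equal(antidominating_y(data.frame(r = "A", t = "B")), 1)
  expect_equal(antidominating_y(data.frame(r = character(0),
                                           t = character(0))), 0)
})

test_that("engine statistics match the plain-R definitions per subnetwork", {
  r <- make_test_ranking(60, seed = 31)
  st <- build_subnetworks(r, structural_config(n = 20))
  ord <- r[order(r$rank), ]
  for (i in seq_along(st$cuts)) {
    sub <- ord[seq_len(st$cuts[i]), c("regulator", "target")]
    und <- unique(t(apply(cbind(sub$regulator, sub$target), 1, sort)))
    ys <- subnetwork_ys(st, i)
    expect_equal(unname(ys["graphlet"]),
                 g4_relative_frequency(count_graphlets(und)))
    expect_equal(unname(ys["regulatory"]), regulatory_y(sub))
    expect_equal(unname(ys["antidominating"]), antidominating_y(sub))
  }
})

test_that("structural cost is the pi-weighted penalty sum", {
  cfg1 <- structural_config(
    penalties = list(structural_penalty("graphlet", a = 1, b = -1,
                                        weight = 1)),
    n = 25)
  r <- make_test_ranking(50, seed = 32)  # single subnetwork of 25 links
  st <- build_subnetworks(r, cfg1)
  sub <- r[order(r$rank), ][1:25, ]
  und <- unique(t(apply(cbind(sub$regulator, sub$target), 1, sort)))
  y <- g4_relative_frequency(count_graphlets(und))
  expect_equal(stack_total_cost(st) - cfg1$alpha * stack_divergence(st),
               0.5 * abs(y - 1))

  # all weights zero: cost identically zero
  cfg0 <- structural_config(
    penalties = list(structural_penalty("graphlet", weight = 0),
                     structural_penalty("regulatory", weight = 0)),
    alpha = 0)
  st0 <- build_subnetworks(r, cfg0)
  expect_equal(stack_total_cost(st0), 0)

  # two subnetworks with identical statistics: cost scales by pi1 + pi2
  r2 <- new_ranking(rep(sprintf("R%d", 1:6), each = 2),
                    sprintf("T%02d", 1:12))
  cfgp <- structural_config(
    penalties = list(structural_penalty("regulatory", a = 1, b = 0,
                                        weight = 1)),
    n = 4, alpha = 0)
  st2 <- build_subnetworks(r2, cfgp)
  y1 <- subnetwork_ys(st2, 1)["regulatory"]
  expect_equal(subnetwork_ys(st2, 1)["regulatory"],
               subnetwork_ys(st2, 2)["regulatory"])
  expect_equal(stack_total_cost(st2), unname((0.5 + 0.25) * y1))
})

test_that("incremental total cost tracks the from-scratch reference", {
  cfg <- structural_config(n = 15)
  r <- make_test_ranking(45, seed = 33)
  st <- build_subnetworks(r, cfg)
  expect_equal(stack_total_cost(st), total_cost_ref(r, cfg),
               tolerance = 1e-12)
  set.seed(34)
  for (k in 1:25) {
    m <- sample(2L, 1L)
    apply_move(st, links = sample(45L, m), new_ranks = sample(45L, m))
  }
  expect_equal(stack_total_cost(st), total_cost_ref(stack_ranking(st), cfg),
               tolerance = 1e-12)
  expect_equal(stack_total_cost(st), stack_scratch_cost(st),
               tolerance = 1e-12)
})

test_that("total cost reduces to the structural term on the identity", {
  cfg <- structural_config(n = 10, alpha = 5)
  r <- make_test_ranking(30, seed = 35)
  expect_equal(total_cost_ref(r, cfg), structural_cost_ref(r, cfg))
  cfg0 <- structural_config(n = 10, alpha = 0)
  set.seed(36)
  rp <- new_ranking(r$regulator, r$target, orig_rank = r$orig_rank,
                    rank = sample(30L))
  expect_equal(total_cost_ref(rp, cfg0), structural_cost_ref(rp, cfg0))
})

test_that("config constructors validate their domains", {
  expect_error(structural_penalty("graphlet", weight = -1), "nonnegative")
  expect_error(structural_config(alpha = -1), "nonnegative")
  expect_error(structural_config(pi_base = 1.5), "decrease")
  expect_error(structural_config(penalties = list()), "length")
})
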