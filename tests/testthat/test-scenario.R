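# Event inference: best ranges, per-branch events, slices, timelines.

make_best <- function(tree, ranges) {
  ages <- node_ages(tree)
  tibble::tibble(node = seq_along(ranges), age = ages[seq_along(ranges)],
                 range = ranges, prob = 1, tie = FALSE,
                 is_tip = seq_along(ranges) <= ape::Ntip(tree))
}

test_that("best range per node takes the argmax with a canonical tie-break", {
  tr <- parse_newick("(t1:1,t2:1):0;", "chronogram")
  tips <- tibble::tibble(species = c("t1", "t2"), range = c("C", "CD"))
  tab <- tibble::tibble(node = c(3, 3), age = 1, range = c("C", "CD"),
                        prob = c(0.7, 0.3))
  out <- best_range_per_node(tab, tr, tips)
  expect_equal(out$range[out$node == 3], "C")
  expect_false(out$tie[out$node == 3])
  # exact tie: smaller canonical state wins and the tie is flagged
  tab2 <- tibble::tibble(node = c(3, 3), age = 1, range = c("D", "C"),
                         prob = c(0.5, 0.5))
  out2 <- best_range_per_node(tab2, tr, tips)
  expect_equal(out2$range[out2$node == 3], "C")
  expect_true(out2$tie[out2$node == 3])
  # tips carry observed ranges with probability 1
  expect_equal(out$range[out$node == 1], "C")
  expect_equal(out$prob[out$node == 1], 1)
  expect_error(best_range_per_node(tab[0, ], tr, tips), "misses node")
})

test_that("branch events are single-area steps with quantile timing", {
  ev <- infer_branch_events("C", "CD", 10, 4)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "dispersal")
  expect_equal(ev$area, "D")
  expect_equal(ev$source, "C")
  expect_equal(ev$time, 7) # midpoint of [4, 10]

  ev2 <- infer_branch_events("CE", "E", 10, 4)
  expect_equal(ev2$kind, "extinction")
  expect_equal(ev2$area, "C")

  # a full range swap needs one loss and one gain; extinction oldest first
  ev3 <- infer_branch_events("C", "D", 9, 3)
  expect_equal(sort(ev3$kind), c("dispersal", "extinction"))
  expect_equal(ev3$time, c(7, 5)) # quantiles 1/3, 2/3 of [3, 9]
  expect_equal(ev3$kind, c("extinction", "dispersal"))

  expect_equal(nrow(infer_branch_events("C", "C", 10, 4)), 0)
})

test_that("per-branch event count equals the symmetric difference size", {
  set.seed(201)
  sp <- dec_state_space(c("A", "B", "C", "D"), 3)
  tr <- simulate_bd_tree(0.1, 0.02, n_tips = 40, seed = 202)
  h <- simulate_dec_history(tr, 0.03, 0.015, sp, seed = 203,
                            root_range = "AB")
  marg <- ancestral_range_marginals(tr, h$tip_ranges, 0.03, 0.015, sp)
  best <- best_range_per_node(marg, tr, h$tip_ranges, sp$areas)
  # raw node-vs-node baseline: |events| = |parent range XOR child range|
  ev_raw <- infer_scenario(best, tr, sp, cladogenesis_aware = FALSE)
  rng <- stats::setNames(range_bits(best$range, sp$areas), best$node)
  for (i in seq_len(nrow(tr$edge))) {
    p <- tr$edge[i, 1]; c_ <- tr$edge[i, 2]
    n_ev <- sum(ev_raw$parent == p & ev_raw$child == c_)
    expect_equal(n_ev, sum(rangediv:::bit_count(
      bitwXor(rng[[as.character(p)]], rng[[as.character(c_)]]))))
  }
  # cladogenesis-aware inference never infers more events than the raw diff
  ev_cl <- infer_scenario(best, tr, sp, cladogenesis_aware = TRUE)
  expect_lte(nrow(ev_cl), nrow(ev_raw))
})

test_that("time-slice summary splits at the boundary and conserves totals", {
  ev <- tibble::tibble(
    kind = c("dispersal", "dispersal", "dispersal", "extinction"),
    area = c("D", "D", "F", "C"),
    source = c("C", "C", "EG", NA),
    time = c(20, 5, 10, 18),
    parent = 10L, child = 11L, from_root = FALSE)
  sl <- summarize_time_slices(ev, boundary = 16)
  expect_equal(sl$totals$dispersals, c(1, 2))
  expect_equal(sl$totals$extinctions, c(1, 0))
  expect_equal(sl$dispersal$count[sl$dispersal$slice == 1 &
                                    sl$dispersal$from == "C"], 1)
  # fractional attribution of a two-area source conserves the total
  f2 <- sl$dispersal[sl$dispersal$slice == 2 & sl$dispersal$to == "F", ]
  expect_equal(sort(f2$from), c("E", "G"))
  expect_equal(f2$count, c(0.5, 0.5))
  expect_equal(sum(sl$dispersal$count), 3)

  # root events excluded when flagged
  ev$from_root <- c(TRUE, FALSE, FALSE, FALSE)
  sl2 <- summarize_time_slices(ev, boundary = 16, exclude_root = TRUE)
  expect_equal(sum(sl2$totals$dispersals), 2)
})

test_that("events-through-time conserves counts in uniform bins", {
  ev <- tibble::tibble(kind = rep(c("dispersal", "extinction"), c(5, 2)),
                       area = "C", source = "C",
                       time = c(2.1, 2.5, 2.9, 7.2, 0.4, 3.3, 3.7),
                       parent = 1L, child = 2L, from_root = FALSE)
  tl <- events_through_time(ev, bin_width = 1, root_age = 10)
  expect_equal(sum(tl$dispersals), 5)
  expect_equal(sum(tl$extinctions), 2)
  expect_equal(tl$dispersals[tl$bin_start == 2], 3)
  # no events: all-zero bins
  tl0 <- events_through_time(ev[0, ], bin_width = 1, root_age = 5)
  expect_true(all(tl0$dispersals == 0) && all(tl0$extinctions == 0))

  # conservation on a simulated scenario with fractional bin edges
  sp <- dec_state_space(c("A", "B", "C"), 2)
  tr <- simulate_bd_tree(0.15, 0, n_tips = 25, seed = 204)
  h <- simulate_dec_history(tr, 0.05, 0.02, sp, seed = 205,
                            root_range = "A")
  tl2 <- events_through_time(h$events, bin_width = 0.75)
  expect_equal(sum(tl2$dispersals) + sum(tl2$extinctions),
               nrow(h$events))
})

test_that("scenario events fall inside their branch age interval", {
  sp <- dec_state_space(c("A", "B", "C", "D"), 3)
  tr <- simulate_bd_tree(0.1, 0, n_tips = 30, seed = 206)
  h <- simulate_dec_history(tr, 0.04, 0.02, sp, seed = 207,
                            root_range = "AB")
  marg <- ancestral_range_marginals(tr, h$tip_ranges, 0.04, 0.02, sp)
  best <- best_range_per_node(marg, tr, h$tip_ranges, sp$areas)
  ev <- infer_scenario(best, tr, sp)
  ages <- node_ages(tr)
  if (nrow(ev) > 0) {
    expect_true(all(ev$time <= ages[ev$parent] + 1e-9))
    expect_true(all(ev$time >= ages[ev$child] - 1e-9))
  }
})
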