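# Switch randomization and the empirical graphlet test.

cat_nm <- enumerate_catalog()

test_that("collapsed-layer swaps preserve per-type per-orientation degrees", {
  g <- random_graph(30, seed = 5, p_phys = 0.15, p_reg = 0.1, p_mutual = 0.3)
  deg <- rpi_degrees(g)
  for (seed in 1:5) {
    r <- switch_randomize(g, randomization_config(rng_seed = seed))
    expect_identical(r$nodes, g$nodes)
    expect_identical(rpi_degrees(r), deg)
    # simple multilabel graph: one labelled edge per pair, no self-loops
    expect_true(all(diag(r$M) == 0L))
    expect_equal(nrow(rpi_edges(r)), nrow(rpi_edges(g)))
  }
})

test_that("raw-layer swaps preserve the physical and directed regulatory degrees", {
  g <- random_graph(30, seed = 6, p_phys = 0.15, p_reg = 0.1, p_mutual = 0.3)
  raw_deg <- function(graph) {
    tab <- rpi_expand(graph)
    n <- graph$nodes
    phys <- tab[tab$interaction_class == "physical", ]
    reg <- tab[tab$interaction_class == "regulatory", ]
    cbind(phys = tabulate(match(c(phys$node_a, phys$node_b), n), length(n)),
          reg_out = tabulate(match(reg$node_a, n), length(n)),
          reg_in = tabulate(match(reg$node_b, n), length(n)))
  }
  cfg <- randomization_config(rng_seed = 2, swap_scope = "raw_layers")
  r <- switch_randomize(g, cfg)
  expect_identical(sort(r$nodes), sort(g$nodes))
  expect_identical(raw_deg(r)[order(r$nodes), ],
                   raw_deg(g)[order(g$nodes), ])
})

test_that("a physical 4-cycle stays simple 2-regular under swaps", {
  g <- mk_graph(phys = pairs_df("a", "b", "b", "c", "c", "d", "d", "a"))
  for (seed in 1:10) {
    r <- switch_randomize(g, randomization_config(rng_seed = seed,
                                                  swaps_per_edge = 20))
    e <- rpi_edges(r)
    expect_true(all(e$edge_type == "P"))
    expect_equal(nrow(e), 4L)
    expect_true(all(rpi_degrees(r)[, "P"] == 2L))
  }
})

test_that("layers with fewer than two edges are left untouched", {
  g <- mk_graph(phys = pairs_df("a", "b", "b", "c", "c", "d", "d", "a"),
                reg = pairs_df("x", "y", "y", "x"))
  expect_message(
    r <- switch_randomize(g, randomization_config(rng_seed = 1)),
    "layer B has < 2 edges")
  e <- rpi_edges(r)
  expect_equal(e[e$edge_type == "B", c("id1", "id2")],
               data.frame(id1 = "x", id2 = "y"), ignore_attr = TRUE)
})

test_that("saturation diagnostics are recorded and plateau on random graphs", {
  g <- random_graph(40, seed = 8, p_phys = 0.2, p_reg = 0.1)
  r <- switch_randomize(g, randomization_config(rng_seed = 4,
                                                swaps_per_edge = 30,
                                                saturation_window = 20))
  d <- attr(r, "swap_diagnostics")
  fr <- d$P$new_edge_fraction
  expect_gt(length(fr), 1L)
  expect_true(all(fr >= 0 & fr <= 1))
  # the trajectory climbs to a plateau rather than oscillating wildly
  expect_gte(fr[length(fr)], fr[1L] - 0.05)
})

test_that("significance arithmetic implements the fewer-than-10 and 1% rules", {
  n <- 1000L
  # graphlet rule: strictly more common in 9 of 1000 replicates -> P < .01
  null9 <- c(rep(11, 9), rep(5, n - 9))
  r <- empirical_p(10, null9, "greater")
  expect_equal(r$exceed_count, 9L)
  expect_equal(r$p, 0.009)
  expect_true(r$exceed_count < ceiling(0.01 * n))
  # boundary: 10 of 1000 -> not significant
  null10 <- c(rep(11, 10), rep(5, n - 10))
  r <- empirical_p(10, null10, "greater")
  expect_equal(r$p, 0.010)
  expect_false(r$exceed_count < ceiling(0.01 * n))
  # orbit rule counts ties: 8 of 1000 medians >= observed -> p = 0.008
  nullm <- c(rep(5, 3), rep(6, 5), rep(2, n - 8))
  r <- empirical_p(5, nullm, "greater_equal")
  expect_equal(r$p, 0.008)
  # pseudo-count option
  expect_equal(empirical_p(10, null9, "greater", pseudocount = TRUE)$p,
               10 / 1001)
})

test_that("overrepresentation test is reproducible and flags zero support", {
  g <- random_graph(20, seed = 12, p_phys = 0.2, p_reg = 0.12)
  cfg <- randomization_config(n_replicates = 20, rng_seed = 77)
  e1 <- graphlet_overrepresentation(g, cat_nm, cfg)
  e2 <- graphlet_overrepresentation(g, cat_nm, cfg)
  expect_identical(e1, e2)
  expect_equal(nrow(e1), 103L)
  # absent graphlets have exceed 0 trivially but are never called
  zs <- e1[e1$zero_support, ]
  expect_true(all(!zs$significant))
  expect_true(all(e1$p >= 0 & e1$p <= 1))
  expect_equal(e1$p, e1$exceed_count / 20)
})
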