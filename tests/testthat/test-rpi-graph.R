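# Ingest, collapse to the 5-type multilabel graph, synthetic generator.

test_that("physical records deduplicate as unordered pairs, regulatory as ordered", {
  ppi <- write_edge_fixture(list(c("A", "B"), c("B", "A")))
  reg <- write_edge_fixture(list(c("A", "B"), c("B", "A")))
  tab <- read_interactions(ppi, reg, quiet = TRUE)
  expect_equal(sum(tab$interaction_class == "physical"), 1L)
  expect_equal(sum(tab$interaction_class == "regulatory"), 2L)
  expect_equal(attr(tab, "n_duplicates"), 1L)
})

test_that("self-regulatory loops are dropped with a warning and tallied", {
  reg <- write_edge_fixture(list(c("A", "A"), c("A", "B")))
  expect_warning(tab <- read_interactions(regulatory_path = reg, quiet = TRUE),
                 "self-referential")
  expect_equal(nrow(tab), 1L)
  expect_equal(attr(tab, "n_self_loops"), 1L)
})

test_that("parse errors name the file; empty files are rejected", {
  bad <- write_edge_fixture(list(c("A", "B"), "lonely"))
  expect_error(read_interactions(bad, quiet = TRUE),
               "malformed row.*line 2", class = "rpig_input_error")
  empty <- write_edge_fixture(list("# only a comment"))
  expect_error(read_interactions(empty, quiet = TRUE), "empty",
               class = "rpig_input_error")
})

test_that("single-file mode with a type column and CSV dialect parse", {
  comb <- write_edge_fixture(list(c("A", "B", "ppi"), c("C", "A", "reg")),
                             ext = "csv", header = c("id1", "id2", "type"))
  tab <- read_interactions(combined_path = comb, quiet = TRUE)
  expect_equal(sort(tab$interaction_class), c("physical", "regulatory"))
  e <- rpi_edges(build_rpi_graph(tab))
  expect_setequal(e$edge_type, c("P", "R"))
  # regulator orientation preserved: C -> A
  expect_equal(e$id1[e$edge_type == "R"], "C")
})

test_that("collapse assigns the five edge types and endpoint orbits", {
  g <- mk_graph(phys = pairs_df("A", "B"))
  e <- rpi_edges(g)
  expect_equal(e$edge_type, "P")
  expect_equal(c(e$orbit_end1, e$orbit_end2), c(1L, 1L))

  # physical + outgoing regulatory: orbit 4 on the regulator end
  g <- mk_graph(phys = pairs_df("A", "B"), reg = pairs_df("A", "B"))
  e <- rpi_edges(g)
  expect_equal(e$edge_type, "PR")
  expect_equal(e$id1, "A")
  expect_equal(c(e$orbit_end1, e$orbit_end2), c(4L, 5L))

  # mutual regulation collapses to a bidirected edge
  g <- mk_graph(reg = pairs_df("A", "B", "B", "A"))
  e <- rpi_edges(g)
  expect_equal(e$edge_type, "B")
  expect_equal(c(e$orbit_end1, e$orbit_end2), c(6L, 6L))

  # all five at once
  g <- mk_graph(phys = pairs_df("A", "B", "C", "D", "E", "F"),
                reg = pairs_df("C", "D", "E", "F", "F", "E", "G", "H",
                               "I", "J", "J", "I"))
  expect_setequal(rpi_edges(g)$edge_type, c("P", "PR", "PB", "R", "B"))
})

test_that("collapse is lossless and invariant under record order", {
  for (seed in 1:5) {
    net <- generate_synthetic_network(25, 0.15, 0.08, p_mutual = 0.2,
                                      seed = seed)
    tab <- net$table
    g <- build_rpi_graph(tab)
    e <- rpi_edges(g)
    tt <- table(factor(e$edge_type, levels = c("P", "R", "PR", "B", "PB")))
    expect_equal(unname(tt[["P"]] + tt[["PR"]] + tt[["PB"]]),
                 sum(tab$interaction_class == "physical"))
    expect_equal(unname(tt[["R"]] + tt[["PR"]] + 2 * tt[["B"]] +
                          2 * tt[["PB"]]),
                 sum(tab$interaction_class == "regulatory"))
    # full record-level reconstruction
    back <- rpi_expand(g)
    key <- function(t) sort(paste(t$interaction_class, t$node_a, t$node_b))
    expect_equal(key(back), key(tab))
    # reorder records -> identical graph
    perm <- sample(nrow(tab))
    tab2 <- interaction_table(
      physical = tab[perm, ][tab$interaction_class[perm] == "physical",
                             c("node_a", "node_b")],
      regulatory = tab[perm, ][tab$interaction_class[perm] == "regulatory",
                               c("node_a", "node_b")])
    expect_identical(build_rpi_graph(tab2)$M, g$M)
  }
})

test_that("synthetic generator honours its stated world", {
  # complete physical layer
  net <- generate_synthetic_network(10, 1, 0, seed = 1)
  g <- build_rpi_graph(net$table)
  expect_equal(nrow(rpi_edges(g)), 45L)
  expect_true(all(rpi_edges(g)$edge_type == "P"))
  # empty layers -> no records, isolated nodes after manual node listing
  net0 <- generate_synthetic_network(50, 0, 0, seed = 1)
  expect_equal(nrow(net0$table), 0L)
  # determinism
  a <- generate_synthetic_network(30, 0.2, 0.1, 0.3, seed = 11,
                                  planted_seed_fraction = 0.2)
  b <- generate_synthetic_network(30, 0.2, 0.1, 0.3, seed = 11,
                                  planted_seed_fraction = 0.2)
  expect_identical(a, b)
  expect_length(a$seeds, 6L)
  # parameter validation
  expect_error(generate_synthetic_network(2, 0.1, 0.1),
               class = "rpig_input_error")
  expect_error(generate_synthetic_network(10, 1.2, 0),
               class = "rpig_input_error")
})

test_that("planted motifs add exactly the intended records", {
  net <- generate_synthetic_network(20, 0, 0, seed = 1,
                                    planted_seed_fraction = 0.5)
  pl <- plant_mixed_motifs(net$table, net$seeds, 2)
  g <- build_rpi_graph(pl$table)
  e <- rpi_edges(g)
  expect_equal(sum(e$edge_type == "P"), 2L)
  expect_equal(sum(e$edge_type == "R"), 4L)
  expect_equal(sort(unique(e$id1[e$edge_type == "R"])),
               sort(pl$triples$regulator))
})
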