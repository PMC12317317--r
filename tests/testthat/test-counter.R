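# Triple enumeration and graphlet/orbit counting.

cat_cnt <- enumerate_catalog()

test_that("connected triple enumeration handles the canonical shapes", {
  # physical triangle: one triple
  g <- mk_graph(phys = pairs_df("A", "B", "B", "C", "A", "C"))
  expect_equal(nrow(enumerate_connected_triples(g)), 1L)
  # star with center c and leaves x, y, z: the three center triples
  g <- mk_graph(phys = pairs_df("c", "x", "c", "y", "c", "z"))
  tri <- enumerate_connected_triples(g)
  expect_equal(nrow(tri), 3L)
  expect_true(all(g$nodes[tri[, "center"]] == "c"))
  # graph with no triples
  g <- mk_graph(phys = pairs_df("A", "B"))
  expect_equal(nrow(enumerate_connected_triples(g)), 0L)
})

test_that("a physical path counts one line graphlet with center/leaf orbits", {
  g <- mk_graph(phys = pairs_df("A", "B", "B", "C"))
  ct <- count_graphlets(g, cat_cnt)
  expect_equal(sum(ct$graphlets[-(1:5)]), 1L)
  gid <- names(which(ct$graphlets[-(1:5)] > 0L))
  expect_equal(cat_cnt$three_node$key[cat_cnt$three_node$graphlet_id == gid],
               "(0,1)(0,1)(1,1)")
  # orbit split: B alone in the center class, A and C share the leaf class
  o3 <- ct$orbits[, 8:266]
  expect_identical(o3["A", ], o3["C", ])
  expect_false(identical(o3["A", ], o3["B", ]))
  # 2-node layer: two P edges, orbit 1 tallies
  expect_equal(unname(ct$graphlets[["P"]]), 2L)
  expect_equal(unname(ct$orbits[, "1"]), c(A = 1L, B = 2L, C = 1L),
               ignore_attr = TRUE)
})

test_that("a collapsed PR edge places the regulator on a (0,4) orbit", {
  g <- mk_graph(phys = pairs_df("A", "B", "B", "C"),
                reg = pairs_df("A", "B"))
  ct <- count_graphlets(g, cat_cnt)
  expect_equal(sum(ct$graphlets[-(1:5)]), 1L)
  gid <- names(which(ct$graphlets[-(1:5)] > 0L))
  row <- cat_cnt$three_node[cat_cnt$three_node$graphlet_id == gid, ]
  expect_equal(row$composition, "mixed")
  expect_equal(row$key, "(0,1)(0,4)(1,5)")
  # A's nonzero 3-node orbit is the one with signature (0,4)
  oa <- which(ct$orbits["A", 8:266] > 0L) + 7L
  sig <- cat_cnt$orbits$signature[match(oa, cat_cnt$orbits$orbit_id)]
  expect_equal(sig, "(0,4)")
})

test_that("counts equal the brute-force canonical-form oracle", {
  for (seed in 1:6) {
    g <- random_graph(18, seed = seed, p_phys = 0.18, p_reg = 0.1,
                      p_mutual = 0.25)
    ct <- count_graphlets(g, cat_cnt)
    or <- oracle_count(g, cat_cnt)
    expect_identical(unname(ct$graphlets), unname(or$graphlets))
    expect_identical(unname(ct$orbits), unname(or$orbits))
  }
})

test_that("node relabelling permutes orbit rows and fixes graphlet counts", {
  g <- random_graph(20, seed = 99, p_phys = 0.2, p_reg = 0.12)
  ct <- count_graphlets(g, cat_cnt)
  # relabel by reversing identifiers (changes the arbitrary node order)
  relabel <- stats::setNames(sprintf("z%02d", rev(seq_along(g$nodes))),
                             g$nodes)
  tab <- rpi_expand(g)
  tab2 <- interaction_table(
    physical = data.frame(a = relabel[tab$node_a], b = relabel[tab$node_b],
      stringsAsFactors = FALSE)[tab$interaction_class == "physical", ],
    regulatory = data.frame(a = relabel[tab$node_a], b = relabel[tab$node_b],
      stringsAsFactors = FALSE)[tab$interaction_class == "regulatory", ])
  ct2 <- count_graphlets(build_rpi_graph(tab2), cat_cnt)
  expect_identical(ct$graphlets, ct2$graphlets)
  expect_identical(ct$orbits[g$nodes, ],
                   ct2$orbits[relabel[g$nodes], ], ignore_attr = TRUE)
})

test_that("conservation identities hold on random graphs", {
  for (seed in 7:9) {
    g <- random_graph(24, seed = seed)
    ct <- count_graphlets(g, cat_cnt, check = TRUE)  # internal assertions
    expect_equal(sum(ct$graphlets[-(1:5)]), ct$n_triples)
    expect_equal(sum(ct$graphlets[1:5]), nrow(rpi_edges(g)))
    csum <- colSums(ct$orbits)
    om <- cat_cnt$orbits
    expect_equal(unname(csum[as.character(om$orbit_id)]),
                 unname(om$class_size * ct$graphlets[om$graphlet_id]))
    # per-node: 3-node orbit totals = triples containing the node
    tri <- enumerate_connected_triples(g)
    per_node <- tabulate(as.vector(tri), nbins = length(g$nodes))
    expect_equal(unname(rowSums(ct$orbits[, 8:266])), per_node)
  }
})

test_that("count output files are written with aligned ids", {
  g <- mk_graph(phys = pairs_df("A", "B", "B", "C"))
  out <- withr::local_tempdir()
  paths <- write_counts(count_graphlets(g, cat_cnt), cat_cnt, out)
  gc <- utils::read.delim(paths[1])
  expect_equal(nrow(gc), 103L)
  expect_equal(sum(gc$count), 3L)  # 2 edges + 1 triple
  om <- utils::read.delim(paths[2], check.names = FALSE)
  expect_equal(dim(om), c(3L, 267L))
})
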