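# Synthetic mixed-network generator.
#
# The generator emulates the shape of curated species interactomes at
# simulation scale: an Erdos-Renyi physical layer over unordered pairs,
# an independent Erdos-Renyi regulatory layer over ordered pairs, an
# optional reciprocation step producing mutual (co-regulating) pairs,
# and an optional planted seed set standing in for a pathway gene list.

#' Generate a random mixed physical/regulatory network
#'
#' Each unordered node pair receives a physical edge with probability
#' `p_physical`; each ordered pair receives a regulatory edge with
#' probability `p_regulatory`; each realized regulatory edge is then made
#' reciprocal with probability `p_mutual`.  A planted seed set of
#' `round(planted_seed_fraction * n_nodes)` nodes is sampled uniformly.
#' Output is deterministic given `seed`.
#'
#' @param n_nodes Number of nodes (>= 3).
#' @param p_physical,p_regulatory,p_mutual Layer probabilities in [0, 1].
#' @param seed Optional RNG seed.
#' @param planted_seed_fraction Fraction of nodes in the planted seed set.
#' @return List with components `table` (an [interaction_table()]) and
#'   `seeds` (character vector of planted seed identifiers).
#' @examples
#' net <- generate_synthetic_network(20, 0.2, 0.05, seed = 1)
#' build_rpi_graph(net$table)
#' @export
generate_synthetic_network <- function(n_nodes, p_physical, p_regulatory,
                                       p_mutual = 0, seed = NULL,
                                       planted_seed_fraction = 0) {
  if (n_nodes < 3L) stop_input("n_nodes must be >= 3")
  for (p in c(p_physical, p_regulatory, p_mutual, planted_seed_fraction)) {
    if (!is.numeric(p) || p < 0 || p > 1) {
      stop_input("probabilities must lie in [0, 1]")
    }
  }
  nodes <- sprintf("n%0*d", nchar(n_nodes), seq_len(n_nodes))
  with_seed_if(seed, {
    pairs <- which(upper.tri(diag(n_nodes)), arr.ind = TRUE)
    keep_p <- stats::runif(nrow(pairs)) < p_physical
    phys <- data.frame(a = nodes[pairs[keep_p, 1L]],
                       b = nodes[pairs[keep_p, 2L]],
                       stringsAsFactors = FALSE)
    ord <- rbind(pairs, pairs[, c(2L, 1L)])
    keep_r <- stats::runif(nrow(ord)) < p_regulatory
    reg <- ord[keep_r, , drop = FALSE]
    if (p_mutual > 0 && nrow(reg) > 0L) {
      recip <- reg[stats::runif(nrow(reg)) < p_mutual, c(2L, 1L),
                   drop = FALSE]
      reg <- rbind(reg, recip)
    }
    reg <- data.frame(a = nodes[reg[, 1L]], b = nodes[reg[, 2L]],
                      stringsAsFactors = FALSE)
    n_seed <- round(planted_seed_fraction * n_nodes)
    seeds <- if (n_seed > 0L) sort(sample(nodes, n_seed)) else character()
    list(table = interaction_table(physical = phys, regulatory = reg),
         seeds = seeds)
  })
}

#' Plant copies of the regulated-pair motif
#'
#' Adds disjoint copies of the mixed triangle in which a regulator
#' targets two physically interacting proteins (edges `c -> x`, `c -> y`
#' regulatory, `x - y` physical) on node triples drawn from `nodes`.
#' Used to build parameter-recovery fixtures with a known enriched
#' graphlet.
#'
#' @param table An [interaction_table()] to extend.
#' @param nodes Candidate nodes; `3 * n_copies` of them are used, in
#'   order, as disjoint (regulator, partner, partner) triples.
#' @param n_copies Number of motif copies.
#' @return List with `table` (extended) and `triples` (a data frame of
#'   the planted regulator/partner assignments).
#' @export
plant_mixed_motifs <- function(table, nodes, n_copies) {
  if (length(nodes) < 3L * n_copies) {
    stop_input("need at least 3 * n_copies candidate nodes")
  }
  idx <- matrix(nodes[seq_len(3L * n_copies)], ncol = 3L, byrow = TRUE)
  trip <- data.frame(regulator = idx[, 1L], partner1 = idx[, 2L],
                     partner2 = idx[, 3L], stringsAsFactors = FALSE)
  phys <- rbind(table[table$interaction_class == "physical",
                      c("node_a", "node_b")],
                data.frame(node_a = trip$partner1, node_b = trip$partner2))
  reg <- rbind(table[table$interaction_class == "regulatory",
                     c("node_a", "node_b")],
               data.frame(node_a = rep(trip$regulator, 2L),
                          node_b = c(trip$partner1, trip$partner2)))
  list(table = interaction_table(physical = phys, regulatory = reg),
       triples = trip)
}
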