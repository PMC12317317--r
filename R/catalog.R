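# Exhaustive catalog of 2- and 3-node graphlets of the RPI edge-type
# alphabet, their automorphism orbits, the sorted-pair encoding used as
# the fast counting key, and an independent canonical form used to prove
# at enumeration time that the encoding discriminates isomorphism classes
# exactly.

PERMS3 <- list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
               c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))

# resolve a 3-node endpoint-code matrix from either a matrix or an
# rpi_graph plus three node identifiers
as_code_matrix3 <- function(x, nodes = NULL) {
  if (inherits(x, "rpi_graph")) {
    if (is.null(nodes) || length(nodes) != 3L) {
      stop_input("supply exactly 3 node identifiers")
    }
    idx <- match(nodes, x$nodes)
    if (anyNA(idx)) stop_input("unknown node(s)")
    m <- x$M[idx, idx, drop = FALSE]
  } else {
    m <- x
  }
  if (!is.matrix(m) || !all(dim(m) == 3L)) {
    stop_input("expected a 3x3 endpoint-code matrix")
  }
  storage.mode(m) <- "integer"
  m
}

n_edges3 <- function(m) {
  sum(m[upper.tri(m)] != 0L | t(m)[upper.tri(m)] != 0L)
}

serialize3 <- function(m) {
  paste0(m[1L, 2L], m[2L, 1L], m[1L, 3L], m[3L, 1L], m[2L, 3L], m[3L, 2L])
}

#' Canonical form of a 3-node labelled subgraph
#'
#' Minimum, over all 6 node permutations, of a fixed serialization of the
#' typed, oriented adjacency.  Two 3-node subgraphs have equal canonical
#' form if and only if they are isomorphic under an edge-type-preserving
#' bijection.  This is the independent oracle against which the
#' sorted-pair encoding is validated.
#'
#' @param x A 3x3 integer endpoint-orbit-code matrix (`x[i, j]` = code of
#'   node `i` toward node `j`, 0 = non-edge), or an `rpi_graph`.
#' @param nodes Three node identifiers when `x` is an `rpi_graph`.
#' @return A character scalar.
#' @export
canonical_form <- function(x, nodes = NULL) {
  m <- as_code_matrix3(x, nodes)
  min(vapply(PERMS3, function(p) serialize3(m[p, p]), ""))
}

# per-node sorted endpoint pairs; row i = sort(codes of node i toward the
# other two nodes)
node_pairs3 <- function(m) {
  o12 <- m[1L, 2L]; o13 <- m[1L, 3L]
  o21 <- m[2L, 1L]; o23 <- m[2L, 3L]
  o31 <- m[3L, 1L]; o32 <- m[3L, 2L]
  rbind(c(min(o12, o13), max(o12, o13)),
        c(min(o21, o23), max(o21, o23)),
        c(min(o31, o32), max(o31, o32)))
}

pair_codes3 <- function(m) {
  p <- node_pairs3(m)
  p[, 1L] * 8L + p[, 2L]
}

key_string_from_codes <- function(codes) {
  codes <- sort(codes)
  paste(sprintf("(%d,%d)", codes %/% 8L, codes %% 8L), collapse = "")
}

key_int_from_codes <- function(codes) {
  codes <- sort(codes)
  codes[1L] * 4096L + codes[2L] * 64L + codes[3L]
}

#' Sorted-pair encoding of a 3-node labelled subgraph
#'
#' Each node's two endpoint orbit codes toward the other nodes (0 for a
#' non-edge) are sorted ascending, and the three resulting pairs are
#' sorted lexicographically.  The encoding is invariant under node
#' relabelling and, over the RPI alphabet, uniquely identifies the
#' isomorphism class (a property proven exhaustively in
#' [enumerate_catalog()]).
#'
#' @inheritParams canonical_form
#' @return A `graphlet_key`: list with `pairs` (3x2 sorted integer
#'   matrix), `key` (display string such as `"(0,1)(0,1)(1,1)"`) and
#'   `key_int` (integer form used for lookup).
#' @examples
#' m <- matrix(0L, 3, 3)           # physical path a - b - c
#' m[1, 2] <- m[2, 1] <- 1L
#' m[2, 3] <- m[3, 2] <- 1L
#' encode_subgraph(m)$key          # "(0,1)(0,1)(1,1)"
#' @export
encode_subgraph <- function(x, nodes = NULL) {
  m <- as_code_matrix3(x, nodes)
  if (n_edges3(m) < 2L) stop_input("subgraph on 3 nodes is not connected")
  codes <- sort(pair_codes3(m))
  structure(
    list(pairs = cbind(codes %/% 8L, codes %% 8L),
         key = key_string_from_codes(codes),
         key_int = key_int_from_codes(codes)),
    class = "graphlet_key")
}

#' @export
print.graphlet_key <- function(x, ...) {
  cat("graphlet_key:", x$key, "\n")
  invisible(x)
}

# orbit partition of the 3 positions under edge-type-preserving
# automorphisms, by explicit search over the 6 permutations
automorphism_partition3 <- function(m) {
  s0 <- serialize3(m)
  auts <- Filter(function(p) serialize3(m[p, p]) == s0, PERMS3)
  cls <- 1:3
  for (p in auts) {
    for (i in 1:3) {
      lo <- min(cls[i], cls[p[i]])
      cls[cls == cls[i] | cls == cls[p[i]]] <- lo
    }
  }
  match(cls, sort(unique(cls)))  # canonical class labels 1..k
}

composition_of_codes <- function(codes) {
  codes <- codes[codes != 0L]
  has_p <- any(codes %in% PHYS_ORBITS)
  has_r <- any(codes %in% REG_ORBITS)
  if (has_p && has_r) "mixed" else if (has_p) "physical_only"
  else "regulatory_only"
}

edge_multiset_of <- function(m) {
  ut <- which(upper.tri(m), arr.ind = TRUE)
  oij <- m[ut]; oji <- m[ut[, c(2L, 1L), drop = FALSE]]
  keep <- oij != 0L
  paste(sort(edge_type_of(oij[keep], oji[keep])), collapse = "+")
}

#' Classify a graphlet's edge composition
#'
#' A graphlet is `mixed` when its edges carry at least one physical
#' component (`P`, `PR`, `PB`) and at least one regulatory component
#' (`R`, `B`, `PR`, `PB`); otherwise `physical_only` or
#' `regulatory_only`.
#'
#' @inheritParams canonical_form
#' @return One of `"mixed"`, `"physical_only"`, `"regulatory_only"`.
#' @export
classify_entry <- function(x, nodes = NULL) {
  m <- as_code_matrix3(x, nodes)
  composition_of_codes(as.vector(m))
}

#' Enumerate the complete 2-/3-node RPI graphlet catalog
#'
#' Brute-forces all assignments of the 8 admissible pair states (absent,
#' `P`, `R` in two orientations, `PR` in two orientations, `B`, `PB`) to
#' the three node pairs of a triple, keeps the connected graphs, groups
#' them by [canonical_form()], computes each class's automorphism orbit
#' partition, and verifies internal consistency: the sorted-pair keys of
#' the classes are pairwise distinct and in bijection with canonical
#' forms, and within every graphlet the partition of positions by sorted
#' pair equals the automorphism partition (so counting can assign orbits
#' by pair signature).  Graphlet ids `G1..G98` follow lexicographic key
#' order; orbit ids are global: 1-7 for the 2-node graphlets, then 8
#' onward grouped by 3-node graphlet.
#'
#' @return A `graphlet_catalog` with data frames `two_node`, `three_node`
#'   and `orbits`, plus lookup structures used by [count_graphlets()].
#' @export
enumerate_catalog <- function() {
  idx_pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  classes <- new.env(parent = emptyenv())
  for (s1 in 1:8) for (s2 in 1:8) for (s3 in 1:8) {
    states <- c(s1, s2, s3)
    if (sum(states > 1L) < 2L) next  # < 2 edges: disconnected
    m <- matrix(0L, 3L, 3L)
    for (q in 1:3) {
      st <- PAIR_STATES[[states[q]]]
      ij <- idx_pairs[[q]]
      m[ij[1L], ij[2L]] <- st[1L]
      m[ij[2L], ij[1L]] <- st[2L]
    }
    cf <- canonical_form(m)
    ent <- classes[[cf]]
    ki <- key_int_from_codes(pair_codes3(m))
    if (is.null(ent)) {
      classes[[cf]] <- list(m = m, keys = ki)
    } else if (!ki %in% ent$keys) {
      ent$keys <- c(ent$keys, ki)
      classes[[cf]] <- ent
    }
  }
  canon <- ls(classes)
  # bijectivity, part 1: one key per isomorphism class
  keys_per_class <- vapply(canon, function(cf) length(classes[[cf]]$keys), 1L)
  if (any(keys_per_class != 1L)) {
    stop_internal("a graphlet class produced multiple sorted-pair keys")
  }
  key_int <- vapply(canon, function(cf) classes[[cf]]$keys, 1L)
  # bijectivity, part 2: one class per key
  if (anyDuplicated(key_int)) {
    stop_internal("two nonisomorphic graphlet classes share a sorted-pair key")
  }
  ord <- order(key_int)
  canon <- canon[ord]
  key_int <- unname(key_int[ord])
  reps <- lapply(canon, function(cf) classes[[cf]]$m)
  ng <- length(canon)

  shape <- character(ng); comp <- character(ng); emset <- character(ng)
  n_ed <- integer(ng); keystr <- character(ng)
  rep_orbits <- matrix(NA_integer_, ng, 3L)
  orbit_sig <- matrix(NA_integer_, ng, 64L)
  orb_graphlet <- integer(0); orb_sig <- integer(0); orb_size <- integer(0)
  next_orbit <- 8L  # 1..7 are the 2-node (edge) orbits
  for (gi in seq_len(ng)) {
    m <- reps[[gi]]
    ne <- n_edges3(m)
    n_ed[gi] <- ne
    shape[gi] <- if (ne == 2L) "line" else "triangle"
    comp[gi] <- composition_of_codes(as.vector(m))
    emset[gi] <- edge_multiset_of(m)
    sig <- pair_codes3(m)
    keystr[gi] <- key_string_from_codes(sig)
    aut <- automorphism_partition3(m)
    # positions with equal sorted pairs must be exactly the orbit classes
    sig_part <- match(sig, unique(sig))
    same_aut <- outer(aut, aut, "==")
    same_sig <- outer(sig_part, sig_part, "==")
    if (!identical(same_aut, same_sig)) {
      stop_internal("pair-signature partition differs from automorphism ",
                    "partition for key ", keystr[gi])
    }
    usig <- sort(unique(sig))
    ids <- next_orbit + seq_along(usig) - 1L
    next_orbit <- next_orbit + length(usig)
    orbit_sig[gi, usig + 1L] <- ids
    rep_orbits[gi, ] <- ids[match(sig, usig)]
    orb_graphlet <- c(orb_graphlet, rep(gi, length(usig)))
    orb_sig <- c(orb_sig, usig)
    orb_size <- c(orb_size, as.integer(table(factor(sig, levels = usig))))
  }

  three_node <- data.frame(
    graphlet_id = paste0("G", seq_len(ng)),
    key = keystr, key_int = key_int, shape = shape, composition = comp,
    n_edges = n_ed, edge_multiset = emset,
    orbit_ids = vapply(seq_len(ng), function(gi)
      paste(rep_orbits[gi, !duplicated(rep_orbits[gi, ])], collapse = ","), ""),
    orbit_class_sizes = vapply(seq_len(ng), function(gi) {
      o <- rep_orbits[gi, ]
      paste(table(factor(o, levels = unique(o))), collapse = ",")
    }, ""),
    stringsAsFactors = FALSE)

  two_node <- data.frame(
    graphlet_id = EDGE_TYPES,
    key = vapply(EDGE_TYPES, function(t)
      sprintf("(%d,%d)", TYPE_END_ORBITS[[t]][1L], TYPE_END_ORBITS[[t]][2L]), ""),
    composition = vapply(EDGE_TYPES, function(t)
      composition_of_codes(TYPE_END_ORBITS[[t]]), ""),
    orbit_ids = vapply(EDGE_TYPES, function(t)
      paste(unique(TYPE_END_ORBITS[[t]]), collapse = ","), ""),
    orbit_class_sizes = vapply(EDGE_TYPES, function(t) {
      o <- TYPE_END_ORBITS[[t]]
      paste(table(factor(o, levels = unique(o))), collapse = ",")
    }, ""),
    stringsAsFactors = FALSE, row.names = NULL)

  orbits2 <- data.frame(
    orbit_id = 1:7,
    graphlet_id = c("P", "R", "R", "PR", "PR", "B", "PB"),
    signature = c("1", "2", "3", "4", "5", "6", "7"),
    class_size = c(2L, 1L, 1L, 1L, 1L, 2L, 2L),
    stringsAsFactors = FALSE)
  orbits3 <- data.frame(
    orbit_id = seq(8L, next_orbit - 1L),
    graphlet_id = paste0("G", orb_graphlet),
    signature = sprintf("(%d,%d)", orb_sig %/% 8L, orb_sig %% 8L),
    class_size = orb_size,
    stringsAsFactors = FALSE)

  cat <- structure(
    list(two_node = two_node, three_node = three_node,
         orbits = rbind(orbits2, orbits3),
         reps = reps, rep_orbits = rep_orbits, orbit_sig = orbit_sig,
         key_int3 = key_int,
         canon3 = stats::setNames(seq_len(ng), canon),
         n_orbits = next_orbit - 1L),
    class = "graphlet_catalog")
  validate_catalog(cat)
  cat
}

# the printed combinatorics of the catalog; enumeration must reproduce
# them exactly or the alphabet/canonicalization is broken
validate_catalog <- function(cat) {
  tn <- cat$three_node
  checks <- c(
    n_three = nrow(tn) == 98L,
    lines = sum(tn$shape == "line") == 28L,
    triangles = sum(tn$shape == "triangle") == 70L,
    mixed = sum(tn$composition == "mixed") == 83L,
    orbits = cat$n_orbits == 266L,  # 7 two-node + 259 three-node
    two_node_cover = identical(
      sort(as.integer(unlist(strsplit(cat$two_node$orbit_ids, ",")))), 1:7)
  )
  if (!all(checks)) {
    stop_internal("catalog consistency failure: ",
                  paste(names(checks)[!checks], collapse = ", "))
  }
  invisible(cat)
}

#' @export
print.graphlet_catalog <- function(x, ...) {
  tn <- x$three_node
  cat(sprintf(
    paste0("graphlet_catalog: 5 two-node (7 orbits), %d three-node ",
           "(%d lines, %d triangles, %d mixed; %d orbits)\n"),
    nrow(tn), sum(tn$shape == "line"), sum(tn$shape == "triangle"),
    sum(tn$composition == "mixed"), x$n_orbits - 7L))
  invisible(x)
}

#' Export the graphlet catalog
#'
#' Writes `catalog_2node.tsv`, `catalog_3node.tsv` and `catalog.json`
#' into `out_dir`.
#'
#' @param catalog A [enumerate_catalog()] result.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of the written paths, invisibly.
#' @export
export_catalog <- function(catalog, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p2 <- file.path(out_dir, "catalog_2node.tsv")
  p3 <- file.path(out_dir, "catalog_3node.tsv")
  pj <- file.path(out_dir, "catalog.json")
  write_tsv(catalog$two_node, p2)
  write_tsv(catalog$three_node[, c("graphlet_id", "key", "shape",
                                   "composition", "edge_multiset",
                                   "orbit_ids", "orbit_class_sizes")], p3)
  jsonlite::write_json(
    list(two_node = catalog$two_node, three_node = catalog$three_node,
         orbits = catalog$orbits),
    pj, dataframe = "rows", auto_unbox = TRUE, pretty = TRUE)
  invisible(c(p2, p3, pj))
}
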