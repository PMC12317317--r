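# Graphlet and orbit counting by exhaustive enumeration of connected
# triples.
#
# Triples are enumerated center-first: for every node c and every pair of
# its neighbours {x, y}, the triple {c, x, y} is connected.  A path
# (x, y non-adjacent) has a unique center and is emitted once; a triangle
# is seen from all three centers and is kept only when c is the
# smallest-index node.  All per-triple work (code lookups, pair sorting,
# key assembly, catalog matching, orbit assignment) is vectorised over
# the full triple list.

#' Enumerate the connected node triples of an RPI graph
#'
#' @param graph An `rpi_graph`.
#' @return Integer matrix with one row per connected triple and columns
#'   `center`, `x`, `y` (node indices into `graph$nodes`); for triangles
#'   the center is the smallest index.
#' @export
enumerate_connected_triples <- function(graph) {
  M <- graph$M
  n <- nrow(M)
  out <- vector("list", n)
  for (cc in seq_len(n)) {
    nb <- which(M[cc, ] != 0L)
    k <- length(nb)
    if (k < 2L) next
    # all pairs x < y of neighbours of cc
    x <- rep.int(nb[-k], rev(seq_len(k - 1L)))
    y <- nb[unlist(lapply(2:k, function(s) s:k), use.names = FALSE)]
    closed <- M[cbind(x, y)] != 0L
    keep <- !closed | (cc < x & cc < y)
    if (any(keep)) out[[cc]] <- cbind(center = cc, x = x[keep], y = y[keep])
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- matrix(integer(), 0L, 3L,
                                  dimnames = list(NULL, c("center", "x", "y")))
  res
}

#' Count every graphlet and node orbit of an RPI graph
#'
#' Tallies all 5 + 98 catalog graphlets (zeros included, so distribution
#' vectors align across graphs) and each node's participation in all
#' 7 + 259 orbits.  Two-node counts come directly from the typed edges;
#' three-node counts come from the connected triples, each encoded with
#' the sorted-pair key and matched against the catalog.
#'
#' @param graph An `rpi_graph`.
#' @param catalog A [enumerate_catalog()] result (enumerated on demand if
#'   omitted).
#' @param check Run the conservation identities after counting
#'   (orbit-column sums equal class size times graphlet count; triple
#'   total matches) and fail loudly on violation.
#' @return An `rpi_graphlet_counts` object: list with `graphlets` (named
#'   count vector over `P,R,PR,B,PB,G1..G98`), `orbits` (nodes x 266
#'   integer matrix, columns named by global orbit id), and `n_triples`.
#' @export
count_graphlets <- function(graph, catalog = NULL, check = TRUE) {
  stopifnot(inherits(graph, "rpi_graph"))
  if (is.null(catalog)) catalog <- enumerate_catalog()
  M <- graph$M
  n <- nrow(M)
  n_orb <- catalog$n_orbits
  orbits <- matrix(0L, n, n_orb,
                   dimnames = list(graph$nodes, as.character(seq_len(n_orb))))

  # --- 2-node graphlets: direct tally of typed edges -------------------
  ut <- which(M != 0L & upper.tri(M), arr.ind = TRUE)
  g2 <- integer(5L); names(g2) <- EDGE_TYPES
  if (nrow(ut) > 0L) {
    oij <- M[ut]
    oji <- M[ut[, c(2L, 1L), drop = FALSE]]
    ty <- edge_type_of(oij, oji)
    tt <- table(factor(ty, levels = EDGE_TYPES))
    g2[names(tt)] <- as.integer(tt)
    # endpoint orbit ids for 2-node graphlets equal the endpoint codes
    inc <- tabulate((c(oij, oji) - 1L) * n + c(ut[, 1L], ut[, 2L]),
                    nbins = 7L * n)
    orbits[, 1:7] <- orbits[, 1:7] + matrix(inc, n, 7L)
  }

  # --- 3-node graphlets ------------------------------------------------
  tri <- enumerate_connected_triples(graph)
  g3 <- integer(98L); names(g3) <- catalog$three_node$graphlet_id
  if (nrow(tri) > 0L) {
    a <- tri[, 1L]; b <- tri[, 2L]; d <- tri[, 3L]
    oab <- M[cbind(a, b)]; oad <- M[cbind(a, d)]
    oba <- M[cbind(b, a)]; obd <- M[cbind(b, d)]
    oda <- M[cbind(d, a)]; odb <- M[cbind(d, b)]
    pa <- pmin(oab, oad) * 8L + pmax(oab, oad)
    pb <- pmin(oba, obd) * 8L + pmax(oba, obd)
    pd <- pmin(oda, odb) * 8L + pmax(oda, odb)
    lo <- pmin(pa, pb, pd)
    hi <- pmax(pa, pb, pd)
    mid <- pa + pb + pd - lo - hi
    gidx <- match(lo * 4096L + mid * 64L + hi, catalog$key_int3)
    if (anyNA(gidx)) {
      stop_internal("connected triple encoding missing from catalog")
    }
    g3 <- g3 + tabulate(gidx, nbins = 98L)
    orb <- c(catalog$orbit_sig[cbind(gidx, pa + 1L)],
             catalog$orbit_sig[cbind(gidx, pb + 1L)],
             catalog$orbit_sig[cbind(gidx, pd + 1L)])
    if (anyNA(orb)) stop_internal("orbit lookup miss during counting")
    inc <- tabulate((orb - 1L) * n + c(a, b, d), nbins = n_orb * n)
    orbits <- orbits + matrix(inc, n, n_orb)
  }

  res <- structure(
    list(graphlets = c(g2, g3), orbits = orbits, n_triples = nrow(tri)),
    class = "rpi_graphlet_counts")
  if (check) validate_counts(res, catalog)
  res
}

# conservation identities tying orbit counts to graphlet counts
validate_counts <- function(counts, catalog) {
  if (sum(counts$graphlets[-(1:5)]) != counts$n_triples) {
    stop_internal("3-node graphlet counts do not sum to the triple total")
  }
  csum <- colSums(counts$orbits)
  om <- catalog$orbits
  expected <- om$class_size *
    counts$graphlets[om$graphlet_id]
  if (!all(csum[as.character(om$orbit_id)] == expected)) {
    stop_internal("orbit-count conservation identity violated")
  }
  invisible(counts)
}

#' @export
print.rpi_graphlet_counts <- function(x, ...) {
  cat(sprintf(
    "rpi_graphlet_counts: %d edge(s), %d connected triple(s), %d of %d graphlet(s) observed\n",
    sum(x$graphlets[1:5]), x$n_triples,
    sum(x$graphlets > 0L), length(x$graphlets)))
  invisible(x)
}

#' Write graphlet and orbit counts
#'
#' Writes `graphlet_counts.tsv` (one row per catalog graphlet, zeros
#' included) and `orbit_counts.tsv` (nodes x orbit-id matrix) into
#' `out_dir`.
#'
#' @param counts A [count_graphlets()] result.
#' @param catalog The catalog used for counting.
#' @param out_dir Output directory.
#' @return The written paths, invisibly.
#' @export
write_counts <- function(counts, catalog, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tn <- catalog$three_node
  df <- data.frame(
    graphlet_id = names(counts$graphlets),
    key = c(catalog$two_node$key, tn$key),
    shape = c(rep("edge", 5L), tn$shape),
    composition = c(catalog$two_node$composition, tn$composition),
    count = as.integer(counts$graphlets),
    stringsAsFactors = FALSE)
  p1 <- file.path(out_dir, "graphlet_counts.tsv")
  write_tsv(df, p1)
  om <- data.frame(node = rownames(counts$orbits), counts$orbits,
                   check.names = FALSE, stringsAsFactors = FALSE)
  p2 <- file.path(out_dir, "orbit_counts.tsv")
  write_tsv(om, p2)
  invisible(c(p1, p2))
}
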