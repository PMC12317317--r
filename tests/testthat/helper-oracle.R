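# Independent brute-force counting oracle.
#
# Examines every one of the C(n,3) node triples, classifies the
# connected ones by an exhaustive permutation-minimizing canonical form
# (its own serialization, not the package's sorted-pair key path), and
# assigns orbits through an explicit isomorphism mapping onto the
# catalog representative.  Deliberately quadratic-cubic and slow.

or_perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))

or_serial <- function(m) {
  paste0(m[1, 2], m[2, 1], m[1, 3], m[3, 1], m[2, 3], m[3, 2])
}

oracle_count <- function(graph, catalog) {
  M <- graph$M
  n <- nrow(M)
  g <- integer(103L)
  names(g) <- c("P", "R", "PR", "B", "PB", catalog$three_node$graphlet_id)
  orb <- matrix(0L, n, catalog$n_orbits,
                dimnames = list(graph$nodes,
                                as.character(seq_len(catalog$n_orbits))))
  type_of <- function(o1, o2) {
    k <- paste(min(o1, o2), max(o1, o2))
    switch(k, "1 1" = "P", "2 3" = "R", "4 5" = "PR", "6 6" = "B",
           "7 7" = "PB", stop("bad pair"))
  }
  # 2-node graphlets: scan all pairs
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (M[i, j] == 0L) next
    g[type_of(M[i, j], M[j, i])] <- g[type_of(M[i, j], M[j, i])] + 1L
    orb[i, M[i, j]] <- orb[i, M[i, j]] + 1L
    orb[j, M[j, i]] <- orb[j, M[j, i]] + 1L
  }
  # 3-node graphlets: every triple
  if (n >= 3L) {
    combs <- utils::combn(n, 3L)
    rep_serials <- vapply(catalog$reps, or_serial, "")
    for (cidx in seq_len(ncol(combs))) {
      trip <- combs[, cidx]
      m <- M[trip, trip]
      ne <- sum(m[upper.tri(m)] != 0L | t(m)[upper.tri(m)] != 0L)
      if (ne < 2L) next
      cf <- min(vapply(or_perms, function(p) or_serial(m[p, p]), ""))
      gi <- unname(catalog$canon3[cf])
      stopifnot(!is.na(gi))
      gid <- catalog$three_node$graphlet_id[gi]
      g[gid] <- g[gid] + 1L
      # explicit isomorphism onto the stored representative
      found <- FALSE
      for (p in or_perms) {
        if (or_serial(m[p, p]) == rep_serials[gi]) {
          # rep position k corresponds to triple node p[k]
          for (k in 1:3) {
            o <- catalog$rep_orbits[gi, k]
            orb[trip[p[k]], o] <- orb[trip[p[k]], o] + 1L
          }
          found <- TRUE
          break
        }
      }
      stopifnot(found)
    }
  }
  list(graphlets = g, orbits = orb)
}
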