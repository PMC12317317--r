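# Degree-preserving randomization of RPI graphs by same-type edge swaps,
# and the empirical graphlet-overrepresentation test built on it.
#
# A swap takes two same-type edges (a,b), (c,d) with four distinct
# incident nodes to (a,d), (c,b) - orientation-preserving for R and PR,
# either re-pairing for symmetric types - and is rejected when it would
# create a self-loop or place an edge on a node pair already occupied by
# any edge (the collapsed graph allows one labelled edge per pair).
# This preserves, per type and per orientation, every node's degree.

#' Randomization configuration
#'
#' @param n_replicates Number of randomized replicates for the
#'   overrepresentation test (the reference protocol uses 1000).
#' @param swaps_per_edge Attempted swaps per layer edge; enough to
#'   saturate the fraction of rewired edges on sparse graphs.
#' @param saturation_window Attempts between saturation measurements.
#' @param saturation_tolerance Early stop when the new-edge fraction
#'   changes less than this across a window.
#' @param rng_seed Optional seed; fixed seed gives an identical replicate
#'   sequence.
#' @param swap_scope `"collapsed_type_layers"` swaps within each of the
#'   five collapsed edge types (preserving all collapsed-type degrees);
#'   `"raw_layers"` swaps the underlying physical and directed regulatory
#'   layers separately and re-collapses.
#' @return A `randomization_config` list.
#' @export
randomization_config <- function(n_replicates = 1000L, swaps_per_edge = 10L,
                                 saturation_window = 100L,
                                 saturation_tolerance = 0.001,
                                 rng_seed = NULL,
                                 swap_scope = c("collapsed_type_layers",
                                                "raw_layers")) {
  stopifnot(n_replicates >= 1L, swaps_per_edge >= 1L,
            saturation_window >= 1L,
            saturation_tolerance > 0, saturation_tolerance < 1)
  structure(list(n_replicates = as.integer(n_replicates),
                 swaps_per_edge = as.integer(swaps_per_edge),
                 saturation_window = as.integer(saturation_window),
                 saturation_tolerance = saturation_tolerance,
                 rng_seed = rng_seed,
                 swap_scope = match.arg(swap_scope)),
            class = "randomization_config")
}

# swap one layer's edge matrix E (m x 2; oriented layers are
# (regulator, target), symmetric layers (lo, hi)).  `occupied` is an
# n x n logical of pairs carrying any edge; `origkeys` the layer's
# original unordered pair keys for saturation tracking.
swap_layer <- function(E, oriented, occupied, n, attempts, window, tol,
                       origkeys) {
  m <- nrow(E)
  fracs <- numeric(0)
  lastfrac <- 0
  accepted <- 0L
  for (t in seq_len(attempts)) {
    e <- sample.int(m, 2L)
    a <- E[e[1L], 1L]; b <- E[e[1L], 2L]
    cc <- E[e[2L], 1L]; dd <- E[e[2L], 2L]
    if (length(unique(c(a, b, cc, dd))) == 4L) {
      if (oriented) {
        n1 <- c(a, dd); n2 <- c(cc, b)
      } else if (stats::runif(1) < 0.5) {
        n1 <- c(a, dd); n2 <- c(cc, b)
      } else {
        n1 <- c(a, cc); n2 <- c(b, dd)
      }
      if (!occupied[n1[1L], n1[2L]] && !occupied[n2[1L], n2[2L]]) {
        occupied[a, b] <- occupied[b, a] <- FALSE
        occupied[cc, dd] <- occupied[dd, cc] <- FALSE
        occupied[n1[1L], n1[2L]] <- occupied[n1[2L], n1[1L]] <- TRUE
        occupied[n2[1L], n2[2L]] <- occupied[n2[2L], n2[1L]] <- TRUE
        E[e[1L], ] <- n1
        E[e[2L], ] <- n2
        accepted <- accepted + 1L
      }
    }
    if (t %% window == 0L) {
      keys <- (pmin(E[, 1L], E[, 2L]) - 1) * n + pmax(E[, 1L], E[, 2L])
      frac <- mean(!(keys %in% origkeys))
      fracs <- c(fracs, frac)
      if (abs(frac - lastfrac) < tol) break
      lastfrac <- frac
    }
  }
  list(E = E, occupied = occupied, accepted = accepted, fracs = fracs)
}

switch_randomize_impl <- function(graph, config) {
  n <- length(graph$nodes)
  M <- graph$M
  e <- rpi_edges(graph)
  i1 <- match(e$id1, graph$nodes)
  i2 <- match(e$id2, graph$nodes)
  diagnostics <- list()

  if (config$swap_scope == "collapsed_type_layers") {
    occupied <- M != 0L
    layers <- split(seq_len(nrow(e)), factor(e$edge_type, levels = EDGE_TYPES))
    Enew <- vector("list", length(EDGE_TYPES))
    names(Enew) <- EDGE_TYPES
    for (ty in EDGE_TYPES) {
      idx <- layers[[ty]]
      E <- cbind(i1[idx], i2[idx])  # regulator first for R/PR
      if (nrow(E) < 2L) {
        if (nrow(E) > 0L) diagnostics[[ty]] <- list(skipped = TRUE)
        Enew[[ty]] <- E
        next
      }
      origkeys <- (pmin(E[, 1L], E[, 2L]) - 1) * n + pmax(E[, 1L], E[, 2L])
      sw <- swap_layer(E, oriented = ty %in% c("R", "PR"), occupied, n,
                       attempts = config$swaps_per_edge * nrow(E),
                       window = config$saturation_window,
                       tol = config$saturation_tolerance, origkeys)
      occupied <- sw$occupied
      Enew[[ty]] <- sw$E
      diagnostics[[ty]] <- list(accepted = sw$accepted,
                                new_edge_fraction = sw$fracs)
    }
    Mnew <- matrix(0L, n, n, dimnames = dimnames(M))
    for (ty in EDGE_TYPES) {
      E <- Enew[[ty]]
      if (nrow(E) == 0L) next
      ends <- TYPE_END_ORBITS[[ty]]
      Mnew[E] <- ends[1L]
      Mnew[E[, c(2L, 1L), drop = FALSE]] <- ends[2L]
    }
    out <- new_rpi_graph(graph$nodes, Mnew)
  } else {
    # raw layers: physical unordered pairs; directed regulatory edges
    phys <- which(e$edge_type %in% c("P", "PR", "PB"))
    regf <- which(e$edge_type %in% c("R", "PR"))    # id1 -> id2
    regb <- which(e$edge_type %in% c("B", "PB"))    # both directions
    Ep <- cbind(pmin(i1[phys], i2[phys]), pmax(i1[phys], i2[phys]))
    Er <- rbind(cbind(i1[regf], i2[regf]),
                cbind(i1[regb], i2[regb]),
                cbind(i2[regb], i1[regb]))
    occp <- matrix(FALSE, n, n)
    if (nrow(Ep) > 0L) {
      occp[Ep] <- TRUE; occp[Ep[, c(2L, 1L), drop = FALSE]] <- TRUE
    }
    if (nrow(Ep) >= 2L) {
      ok <- (pmin(Ep[, 1L], Ep[, 2L]) - 1) * n + pmax(Ep[, 1L], Ep[, 2L])
      sw <- swap_layer(Ep, FALSE, occp, n,
                       config$swaps_per_edge * nrow(Ep),
                       config$saturation_window,
                       config$saturation_tolerance, ok)
      Ep <- sw$E
      diagnostics$physical <- list(accepted = sw$accepted,
                                   new_edge_fraction = sw$fracs)
    }
    # regulatory: ordered-pair occupancy (a duplicate directed edge is
    # forbidden; the reverse direction is allowed and collapses to B/PB)
    occr <- matrix(FALSE, n, n)
    if (nrow(Er) > 0L) occr[Er] <- TRUE
    if (nrow(Er) >= 2L) {
      m <- nrow(Er)
      attempts <- config$swaps_per_edge * m
      accepted <- 0L
      for (t in seq_len(attempts)) {
        ee <- sample.int(m, 2L)
        a <- Er[ee[1L], 1L]; b <- Er[ee[1L], 2L]
        cc <- Er[ee[2L], 1L]; dd <- Er[ee[2L], 2L]
        if (a == dd || cc == b || (a == cc && b == dd)) next
        if (occr[a, dd] || occr[cc, b]) next
        occr[a, b] <- FALSE; occr[cc, dd] <- FALSE
        occr[a, dd] <- TRUE; occr[cc, b] <- TRUE
        Er[ee[1L], ] <- c(a, dd)
        Er[ee[2L], ] <- c(cc, b)
        accepted <- accepted + 1L
      }
      diagnostics$regulatory <- list(accepted = accepted,
                                     new_edge_fraction = numeric(0))
    }
    nodes <- graph$nodes
    tab <- interaction_table(
      physical = data.frame(a = nodes[Ep[, 1L]], b = nodes[Ep[, 2L]]),
      regulatory = data.frame(a = nodes[Er[, 1L]], b = nodes[Er[, 2L]]))
    out <- build_rpi_graph(tab)
    # keep isolated nodes lost in rebuild
    if (length(out$nodes) < n) {
      Mfull <- matrix(0L, n, n, dimnames = list(nodes, nodes))
      Mfull[out$nodes, out$nodes] <- out$M
      out <- new_rpi_graph(nodes, Mfull)
    }
  }
  attr(out, "swap_diagnostics") <- diagnostics
  out
}

#' Degree-preserving switch randomization
#'
#' Produces a randomized graph with the same node set and, for every
#' edge type and orientation, the same degree sequence as the input (in
#' `"collapsed_type_layers"` scope; `"raw_layers"` scope preserves the
#' physical-layer and directed-regulatory-layer degrees before
#' re-collapsing).  Saturation of the fraction of rewired edges is
#' tracked per attempt window and available as
#' `attr(result, "swap_diagnostics")`.
#'
#' @param graph An `rpi_graph`.
#' @param config A [randomization_config()].
#' @return A randomized `rpi_graph`.
#' @export
switch_randomize <- function(graph, config = randomization_config()) {
  stopifnot(inherits(graph, "rpi_graph"),
            inherits(config, "randomization_config"))
  out <- with_seed_if(config$rng_seed, switch_randomize_impl(graph, config))
  d <- attr(out, "swap_diagnostics")
  for (ty in names(d)) {
    if (isTRUE(d[[ty]]$skipped)) {
      message(sprintf("layer %s has < 2 edges; left untouched", ty))
    }
  }
  out
}

#' Empirical exceedance of an observed statistic over a null sample
#'
#' @param observed Observed value.
#' @param null_values Numeric vector of null replicate values.
#' @param comparison `"greater"` counts replicates strictly above the
#'   observed value; `"greater_equal"` counts ties as exceedances.
#' @param pseudocount If `TRUE`, report `(exceed + 1) / (n + 1)` instead
#'   of the plain fraction.
#' @return List with `exceed_count` and `p`.
#' @export
empirical_p <- function(observed, null_values,
                        comparison = c("greater", "greater_equal"),
                        pseudocount = FALSE) {
  comparison <- match.arg(comparison)
  exceed <- if (comparison == "greater") sum(null_values > observed)
            else sum(null_values >= observed)
  n <- length(null_values)
  p <- if (pseudocount) (exceed + 1) / (n + 1) else exceed / n
  list(exceed_count = as.integer(exceed), p = p)
}

#' Graphlet overrepresentation against the switch-randomized null
#'
#' Counts graphlets in the observed graph and in `n_replicates`
#' independently randomized graphs.  A graphlet is significantly
#' overrepresented when its count is exceeded in fewer than
#' `ceiling(alpha * n_replicates)` replicates (with the reference 1000
#' replicates and alpha 0.01: fewer than 10, i.e. P < .01).  Graphlets
#' absent from the observed graph are flagged `zero_support` and never
#' called significant.
#'
#' @param graph An `rpi_graph` (typically a seed subnetwork).
#' @param catalog A [enumerate_catalog()] result.
#' @param config A [randomization_config()].
#' @param comparison Exceedance rule; the graphlet test uses strict
#'   `"greater"` by default.
#' @param alpha Significance level for the exceedance rule.
#' @param pseudocount Passed to [empirical_p()].
#' @return A `graphlet_enrichment` data frame with columns
#'   `graphlet_id`, `key`, `observed`, `null_mean`, `null_sd`,
#'   `exceed_count`, `p`, `significant`, `zero_support`; the replicate
#'   count matrix is in `attr(x, "null_counts")`.
#' @export
graphlet_overrepresentation <- function(graph, catalog = NULL,
                                        config = randomization_config(),
                                        comparison = c("greater",
                                                       "greater_equal"),
                                        alpha = 0.01, pseudocount = FALSE) {
  comparison <- match.arg(comparison)
  if (is.null(catalog)) catalog <- enumerate_catalog()
  observed <- count_graphlets(graph, catalog)$graphlets
  nr <- config$n_replicates
  nulls <- with_seed_if(config$rng_seed, {
    vapply(seq_len(nr), function(r) {
      count_graphlets(switch_randomize_impl(graph, config), catalog,
                      check = FALSE)$graphlets
    }, observed)
  })
  nulls <- t(nulls)  # replicates x graphlets
  exceed <- if (comparison == "greater") {
    colSums(nulls > rep(observed, each = nr))
  } else {
    colSums(nulls >= rep(observed, each = nr))
  }
  p <- if (pseudocount) (exceed + 1) / (nr + 1) else exceed / nr
  res <- data.frame(
    graphlet_id = names(observed),
    key = c(catalog$two_node$key, catalog$three_node$key),
    observed = as.integer(observed),
    null_mean = colMeans(nulls),
    null_sd = apply(nulls, 2L, stats::sd),
    exceed_count = as.integer(exceed),
    p = p,
    significant = exceed < ceiling(alpha * nr) & observed > 0L,
    zero_support = observed == 0L,
    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "null_counts") <- nulls
  class(res) <- c("graphlet_enrichment", "data.frame")
  res
}

#' Write a graphlet enrichment table
#'
#' @param result A [graphlet_overrepresentation()] result.
#' @param path Output TSV path.
#' @param null_matrix_path Optional path for the per-replicate count
#'   matrix.
#' @return `path`, invisibly.
#' @export
write_graphlet_enrichment <- function(result, path,
                                      null_matrix_path = NULL) {
  write_tsv(as.data.frame(result), path)
  if (!is.null(null_matrix_path)) {
    nm <- attr(result, "null_counts")
    write_tsv(data.frame(replicate = seq_len(nrow(nm)), nm,
                         check.names = FALSE), null_matrix_path)
  }
  invisible(path)
}
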