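# Median-based orbit overrepresentation test for a protein set, against
# random node sets of the same size, plus export of per-orbit member
# lists for downstream annotation tools.

#' Orbit overrepresentation of a protein set
#'
#' For every orbit, compares the median orbit count of the query
#' proteins with the medians of `n_samples` node sets of the same size
#' sampled uniformly without replacement from all network nodes.  An
#' orbit is significantly overrepresented when fewer than
#' `alpha * n_samples` sample medians are equal to or larger than the
#' observed median (the "equal to or larger" direction is deliberate and
#' differs from the strict rule of the graphlet test).
#'
#' @param orbit_matrix A [count_graphlets()] result or its `orbits`
#'   matrix (nodes x orbit ids).
#' @param query_set Character vector of query node identifiers; members
#'   absent from the matrix are dropped with a warning.
#' @param n_samples Number of random node sets (reference protocol:
#'   1000).
#' @param rng_seed Optional seed for reproducible sampling.
#' @param alpha Significance level.
#' @return An `orbit_enrichment` data frame with columns `orbit_id`,
#'   `graphlet_id`, `observed_median`, `null_median_mean`, `ge_count`,
#'   `p`, `significant`, `n_members`; per-orbit query members with
#'   nonzero counts are in `attr(x, "members")` and the null medians in
#'   `attr(x, "null_medians")`.
#' @export
orbit_overrepresentation <- function(orbit_matrix, query_set,
                                     n_samples = 1000L, rng_seed = NULL,
                                     alpha = 0.01) {
  if (inherits(orbit_matrix, "rpi_graphlet_counts")) {
    orbit_matrix <- orbit_matrix$orbits
  }
  stopifnot(is.matrix(orbit_matrix), n_samples >= 1L)
  nodes <- rownames(orbit_matrix)
  query <- intersect(unique(query_set), nodes)
  absent <- setdiff(unique(query_set), nodes)
  if (length(absent) > 0L) {
    warning(sprintf("%d query node(s) absent from the orbit matrix dropped",
                    length(absent)), call. = FALSE)
  }
  if (length(query) == 0L) stop_input("query set empty after filtering")
  q <- length(query)
  observed <- apply(orbit_matrix[query, , drop = FALSE], 2L, stats::median)
  nm <- with_seed_if(rng_seed, {
    vapply(seq_len(n_samples), function(s) {
      idx <- sample.int(nrow(orbit_matrix), q)
      apply(orbit_matrix[idx, , drop = FALSE], 2L, stats::median)
    }, observed)
  })
  # samples x orbits, robust to a single-orbit matrix
  null_medians <- if (is.matrix(nm)) t(nm) else matrix(nm, ncol = 1L)
  ge <- colSums(null_medians >= rep(observed, each = n_samples))
  p <- ge / n_samples
  members <- lapply(seq_len(ncol(orbit_matrix)), function(o) {
    query[orbit_matrix[query, o] > 0L]
  })
  names(members) <- colnames(orbit_matrix)
  res <- data.frame(
    orbit_id = as.integer(colnames(orbit_matrix)),
    observed_median = unname(observed),
    null_median_mean = unname(colMeans(null_medians)),
    ge_count = as.integer(ge),
    p = unname(p),
    significant = unname(p < alpha),
    n_members = lengths(members),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "members") <- members
  attr(res, "null_medians") <- null_medians
  class(res) <- c("orbit_enrichment", "data.frame")
  res
}

# annotate an orbit enrichment table with its graphlet and composition
annotate_orbit_enrichment <- function(result, catalog) {
  om <- catalog$orbits
  idx <- match(result$orbit_id, om$orbit_id)
  result$graphlet_id <- om$graphlet_id[idx]
  gmap <- c(stats::setNames(catalog$two_node$composition,
                            catalog$two_node$graphlet_id),
            stats::setNames(catalog$three_node$composition,
                            catalog$three_node$graphlet_id))
  kmap <- c(stats::setNames(catalog$two_node$key,
                            catalog$two_node$graphlet_id),
            stats::setNames(catalog$three_node$key,
                            catalog$three_node$graphlet_id))
  result$key <- unname(kmap[result$graphlet_id])
  result$composition <- unname(gmap[result$graphlet_id])
  result
}

#' Export per-orbit member lists
#'
#' Writes one plain-text identifier list per retained orbit (for use
#' with external annotation/enrichment services), optionally restricted
#' to significant orbits and/or orbits of mixed graphlets.
#'
#' @param result An [orbit_overrepresentation()] result.
#' @param catalog A [enumerate_catalog()] result (for graphlet
#'   composition).
#' @param out_dir Output directory.
#' @param significant_only,mixed_only Filters applied before export.
#' @return Paths of the written member lists, invisibly (empty when no
#'   orbit passes the filter, with a summary message).
#' @export
export_orbit_members <- function(result, catalog, out_dir,
                                 significant_only = TRUE,
                                 mixed_only = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ann <- annotate_orbit_enrichment(result, catalog)
  keep <- rep(TRUE, nrow(ann))
  if (significant_only) keep <- keep & ann$significant
  if (mixed_only) keep <- keep & ann$composition == "mixed"
  keep <- keep & ann$n_members > 0L
  if (!any(keep)) {
    message("no orbit passes the export filter; nothing written")
    return(invisible(character()))
  }
  members <- attr(result, "members")
  paths <- vapply(which(keep), function(i) {
    p <- file.path(out_dir, sprintf("orbit_%03d_members.txt",
                                    ann$orbit_id[i]))
    writeLines(members[[as.character(ann$orbit_id[i])]], p)
    p
  }, "")
  invisible(paths)
}

#' Write an orbit enrichment table
#'
#' @param result An [orbit_overrepresentation()] result.
#' @param catalog A [enumerate_catalog()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_orbit_enrichment <- function(result, catalog, path) {
  ann <- annotate_orbit_enrichment(result, catalog)
  cols <- c("orbit_id", "graphlet_id", "key", "composition",
            "observed_median", "null_median_mean", "ge_count", "p",
            "significant", "n_members")
  write_tsv(as.data.frame(ann)[, cols], path)
}
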