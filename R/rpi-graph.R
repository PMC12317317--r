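# Ingest of physical / regulatory interaction records and construction of
# the collapsed multilabel RPI graph.
#
# The RPI graph is stored as a dense integer matrix `M` of endpoint orbit
# codes: M[i, j] = orbit code of node i toward node j (0 = no edge).  The
# support of M is symmetric (every edge type gives both endpoints a
# nonzero code) and codes of opposite ends are consistent partners.
# Dense storage keeps triple enumeration fully vectorised; the intended
# scale is the sparse, genome-scale-down networks used for simulation and
# pathway-level analysis (up to a few thousand nodes).

#' Construct an interaction table
#'
#' Normalizes raw interaction records: identifiers are whitespace-stripped
#' (case-sensitive, no other normalization), self-referential records are
#' dropped with a warning, physical pairs are deduplicated as unordered
#' pairs and regulatory pairs as ordered (regulator, target) pairs.
#'
#' @param physical Two-column data frame or matrix of physical pairs.
#' @param regulatory Two-column data frame or matrix of regulatory pairs,
#'   regulator in the first column.
#' @return An `interaction_table`: a data frame with columns `node_a`,
#'   `node_b`, `interaction_class` and attributes `n_duplicates`,
#'   `n_self_loops` tallying records removed during normalization.
#' @export
interaction_table <- function(physical = NULL, regulatory = NULL) {
  norm <- function(x, class) {
    if (is.null(x) || NROW(x) == 0L) {
      return(data.frame(node_a = character(), node_b = character(),
                        interaction_class = character(),
                        stringsAsFactors = FALSE))
    }
    x <- as.data.frame(x, stringsAsFactors = FALSE)
    a <- trimws(as.character(x[[1L]]))
    b <- trimws(as.character(x[[2L]]))
    if (any(!nzchar(a)) || any(!nzchar(b))) {
      stop_input("empty identifier in ", class, " records")
    }
    data.frame(node_a = a, node_b = b, interaction_class = class,
               stringsAsFactors = FALSE)
  }
  tab <- rbind(norm(physical, "physical"), norm(regulatory, "regulatory"))

  self <- tab$node_a == tab$node_b
  n_self <- sum(self)
  if (n_self > 0L) {
    warning(sprintf("dropped %d self-referential record(s)", n_self),
            call. = FALSE)
    tab <- tab[!self, , drop = FALSE]
  }

  # physical pairs are unordered: canonical order before dedup
  phys <- tab$interaction_class == "physical"
  lo <- ifelse(phys, pmin(tab$node_a, tab$node_b), tab$node_a)
  hi <- ifelse(phys, pmax(tab$node_a, tab$node_b), tab$node_b)
  key <- paste(tab$interaction_class, lo, hi, sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  tab <- tab[!dup, , drop = FALSE]
  tab$node_a[phys[!dup]] <- lo[!dup][phys[!dup]]
  tab$node_b[phys[!dup]] <- hi[!dup][phys[!dup]]
  rownames(tab) <- NULL

  structure(tab, n_duplicates = n_dup, n_self_loops = n_self,
            class = c("interaction_table", "data.frame"))
}

#' @export
print.interaction_table <- function(x, ...) {
  cat(sprintf(
    "interaction_table: %d physical, %d regulatory record(s)\n",
    sum(x$interaction_class == "physical"),
    sum(x$interaction_class == "regulatory")))
  cat(sprintf("  (%d duplicate(s) and %d self-loop(s) removed at ingest)\n",
              attr(x, "n_duplicates"), attr(x, "n_self_loops")))
  invisible(x)
}

read_edge_file <- function(path, sep = NULL, what = "interaction") {
  if (!file.exists(path)) stop_input("file not found: ", path)
  sep <- guess_sep(path, sep)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop_input("empty ", what, " file: ", path)
  fields <- strsplit(lines, sep, fixed = TRUE)
  if (looks_like_header(fields[[1L]])) {
    fields <- fields[-1L]
    lineno <- lineno[-1L]
    if (length(fields) == 0L) stop_input("empty ", what, " file: ", path)
  }
  bad <- which(vapply(fields, length, 1L) < 2L)
  if (length(bad) > 0L) {
    stop_input(sprintf("malformed row in %s at line %d (need >= 2 columns)",
                       path, lineno[bad[1L]]))
  }
  data.frame(
    a = trimws(vapply(fields, `[[`, "", 1L)),
    b = trimws(vapply(fields, `[[`, "", 2L)),
    extra = vapply(fields, function(f) if (length(f) >= 3L) trimws(f[[3L]]) else "",
                   ""),
    stringsAsFactors = FALSE)
}

#' Read interaction edge lists
#'
#' Reads plain-text edge lists in either two-file mode (one physical, one
#' regulatory file, columns `[id1, id2]`) or single-file mode (columns
#' `[id1, id2, type]` with type `ppi`/`physical` or `reg`/`regulatory`).
#' Lines starting with `#` are skipped; a header row is detected
#' heuristically; TSV is assumed unless the extension is `.csv` or `sep`
#' is given.  Regulatory rows are ordered regulator-to-target.
#'
#' @param physical_path,regulatory_path Paths for two-file mode.
#' @param combined_path Path for single-file mode (three columns).
#' @param sep Field separator; default inferred from the file extension.
#' @param quiet Suppress the ingest summary message.
#' @return An [interaction_table()].
#' @export
read_interactions <- function(physical_path = NULL, regulatory_path = NULL,
                              combined_path = NULL, sep = NULL,
                              quiet = FALSE) {
  if (!is.null(combined_path)) {
    raw <- read_edge_file(combined_path, sep, "interaction")
    cls <- tolower(raw$extra)
    is_phys <- cls %in% c("ppi", "p", "physical", "phys")
    is_reg  <- cls %in% c("reg", "r", "regulatory")
    if (any(!is_phys & !is_reg)) {
      stop_input("unrecognized interaction type value(s) in ", combined_path,
                 ": ", paste(unique(cls[!is_phys & !is_reg]), collapse = ", "))
    }
    phys <- raw[is_phys, c("a", "b")]
    reg  <- raw[is_reg, c("a", "b")]
  } else {
    if (is.null(physical_path) && is.null(regulatory_path)) {
      stop_input("supply physical_path/regulatory_path or combined_path")
    }
    phys <- if (is.null(physical_path)) NULL else
      read_edge_file(physical_path, sep, "physical")[, c("a", "b")]
    reg <- if (is.null(regulatory_path)) NULL else
      read_edge_file(regulatory_path, sep, "regulatory")[, c("a", "b")]
  }
  tab <- interaction_table(physical = phys, regulatory = reg)
  if (!quiet) {
    message(sprintf(
      "read %d physical and %d regulatory record(s); removed %d duplicate(s), %d self-loop(s)",
      sum(tab$interaction_class == "physical"),
      sum(tab$interaction_class == "regulatory"),
      attr(tab, "n_duplicates"), attr(tab, "n_self_loops")))
  }
  tab
}

#' Collapse interaction records into a multilabel RPI graph
#'
#' For every node pair the unique combination of (physical edge present?)
#' and (regulatory edges: none / one direction / both directions) is
#' mapped to one of the five edge types `P`, `R`, `PR`, `B`, `PB`; the
#' endpoint orbit labels 1..7 follow from the type (see
#' [edge_type_of()]).  The collapse is lossless: the deduplicated input
#' records are recoverable from the typed edges.
#'
#' @param table An [interaction_table()].
#' @return An `rpi_graph` object with components `nodes` (sorted
#'   identifier vector) and `M` (integer endpoint-orbit-code matrix).
#' @examples
#' tab <- interaction_table(
#'   physical = data.frame(a = "A", b = "B"),
#'   regulatory = data.frame(reg = "A", tgt = "B"))
#' g <- build_rpi_graph(tab)
#' rpi_edges(g)  # one PR edge, orbit 4 on the regulator end
#' @export
build_rpi_graph <- function(table) {
  stopifnot(inherits(table, "interaction_table"))
  nodes <- sort(unique(c(table$node_a, table$node_b)))
  n <- length(nodes)
  M <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  if (n > 0L) {
    ia <- match(table$node_a, nodes)
    ib <- match(table$node_b, nodes)
    phys <- table$interaction_class == "physical"
    P <- matrix(FALSE, n, n)
    P[cbind(ia[phys], ib[phys])] <- TRUE
    P <- P | t(P)
    D <- matrix(FALSE, n, n)  # D[i, j]: i regulates j
    D[cbind(ia[!phys], ib[!phys])] <- TRUE
    out_ <- D & !t(D)   # one-direction regulatory, i -> j
    in_  <- t(D) & !D
    both <- D & t(D)
    M[P  & !out_ & !in_ & !both] <- 1L  # P
    M[!P & out_]                 <- 2L  # R, regulator end
    M[!P & in_]                  <- 3L
    M[P  & out_]                 <- 4L  # PR, regulator end
    M[P  & in_]                  <- 5L
    M[!P & both]                 <- 6L  # B
    M[P  & both]                 <- 7L  # PB
  }
  new_rpi_graph(nodes, M)
}

new_rpi_graph <- function(nodes, M) {
  structure(list(nodes = nodes, M = M), class = "rpi_graph")
}

#' @export
print.rpi_graph <- function(x, ...) {
  e <- rpi_edges(x)
  tt <- table(factor(e$edge_type, levels = EDGE_TYPES))
  cat(sprintf("rpi_graph: %d nodes, %d labelled edge(s)\n",
              length(x$nodes), nrow(e)))
  cat("  ", paste(sprintf("%s=%d", names(tt), tt), collapse = " "), "\n")
  invisible(x)
}

#' Labelled edge list of an RPI graph
#'
#' @param graph An `rpi_graph`.
#' @return Data frame with columns `id1`, `id2`, `edge_type`,
#'   `orbit_end1`, `orbit_end2`; for oriented types (`R`, `PR`) `id1` is
#'   the regulator.
#' @export
rpi_edges <- function(graph) {
  stopifnot(inherits(graph, "rpi_graph"))
  M <- graph$M
  idx <- which(M != 0L & upper.tri(M), arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(data.frame(id1 = character(), id2 = character(),
                      edge_type = character(), orbit_end1 = integer(),
                      orbit_end2 = integer(), stringsAsFactors = FALSE))
  }
  oij <- M[idx]
  oji <- M[idx[, c(2L, 1L), drop = FALSE]]
  ty <- edge_type_of(oij, oji)
  # orient regulator first for R / PR
  flip <- oij > oji  # regulator end has the smaller code within a type pair
  i1 <- ifelse(flip, idx[, 2L], idx[, 1L])
  i2 <- ifelse(flip, idx[, 1L], idx[, 2L])
  data.frame(id1 = graph$nodes[i1], id2 = graph$nodes[i2],
             edge_type = ty,
             orbit_end1 = ifelse(flip, oji, oij),
             orbit_end2 = ifelse(flip, oij, oji),
             stringsAsFactors = FALSE)
}

#' Write the collapsed RPI edge list
#'
#' @param graph An `rpi_graph`.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_rpi_edges <- function(graph, path) {
  e <- rpi_edges(graph)
  e <- e[order(e$id1, e$id2), , drop = FALSE]
  write_tsv(e, path)
}

#' Per-type, per-orientation node degrees
#'
#' Degrees of every node in each collapsed type layer; oriented layers
#' (`R`, `PR`) are split into out- (regulator) and in- (target) degrees.
#' Used to verify the switch-randomization invariant.
#'
#' @param graph An `rpi_graph`.
#' @return Integer matrix, nodes x (`P`, `B`, `PB`, `R_out`, `R_in`,
#'   `PR_out`, `PR_in`).
#' @export
rpi_degrees <- function(graph) {
  M <- graph$M
  cbind(P      = rowSums(M == 1L),
        B      = rowSums(M == 6L),
        PB     = rowSums(M == 7L),
        R_out  = rowSums(M == 2L),
        R_in   = rowSums(M == 3L),
        PR_out = rowSums(M == 4L),
        PR_in  = rowSums(M == 5L))
}

#' Induced subgraph on a node subset
#'
#' @param graph An `rpi_graph`.
#' @param nodes Identifiers to keep (must be present in the graph).
#' @return The induced `rpi_graph` (labels of surviving edges unchanged).
#' @export
rpi_subgraph <- function(graph, nodes) {
  idx <- match(nodes, graph$nodes)
  if (anyNA(idx)) stop_input("unknown node(s): ",
                             paste(nodes[is.na(idx)], collapse = ", "))
  idx <- sort(idx)
  new_rpi_graph(graph$nodes[idx], graph$M[idx, idx, drop = FALSE])
}

#' Reconstruct interaction records from a collapsed graph
#'
#' Inverse of [build_rpi_graph()]: expands the typed edges back to the
#' deduplicated physical and regulatory records (self-loops excepted,
#' which were dropped at ingest).
#'
#' @param graph An `rpi_graph`.
#' @return An [interaction_table()].
#' @export
rpi_expand <- function(graph) {
  e <- rpi_edges(graph)
  phys <- e[e$edge_type %in% c("P", "PR", "PB"), c("id1", "id2")]
  reg1 <- e[e$edge_type %in% c("R", "PR"), c("id1", "id2")]    # id1 -> id2
  regb <- e[e$edge_type %in% c("B", "PB"), c("id1", "id2")]
  regb_rev <- data.frame(id1 = regb$id2, id2 = regb$id1,
                         stringsAsFactors = FALSE)
  reg <- rbind(reg1, regb, regb_rev)
  interaction_table(physical = phys, regulatory = reg)
}
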