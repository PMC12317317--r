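# Random walk with restart from a seed protein set and extraction of the
# minimal score-ranked subnetwork covering a target fraction of seeds.

#' RWR configuration
#'
#' @param restart_probability Probability of teleporting back to the
#'   seed distribution at each step (the reference protocol restarts at
#'   the pathway proteins with 0.85).
#' @param tolerance L1 convergence threshold on the score vector.
#' @param max_iterations Iteration cap.
#' @param traversal `"symmetric"` walks every labelled edge in both
#'   directions (proximity semantics); `"directed_forward"` follows
#'   physical edges both ways but regulatory edges only from regulator
#'   to target.
#' @return An `rwr_config` list.
#' @export
rwr_config <- function(restart_probability = 0.85, tolerance = 1e-10,
                       max_iterations = 1000L,
                       traversal = c("symmetric", "directed_forward")) {
  stopifnot(restart_probability > 0, restart_probability < 1,
            tolerance > 0, max_iterations >= 1L)
  structure(list(restart_probability = restart_probability,
                 tolerance = tolerance,
                 max_iterations = as.integer(max_iterations),
                 traversal = match.arg(traversal)),
            class = "rwr_config")
}

# allowed step matrix A[i, j] = 1 if the walk may move i -> j
walk_adjacency <- function(graph, traversal) {
  M <- graph$M
  if (traversal == "symmetric") {
    A <- (M != 0L) * 1
  } else {
    # forward: physical component walks both ways; regulatory only
    # regulator -> target.  Code 3 (incoming regulatory only) is the one
    # non-walkable direction.
    A <- (M != 0L & M != 3L) * 1
  }
  A
}

#' Random-walk-with-restart node scores
#'
#' Iterates `s <- (1 - alpha) * T s + alpha * r` to its fixed point,
#' where `alpha` is the restart probability, `r` is uniform over the
#' seeds present in the graph, and `T` is the column-normalized
#' transition matrix over the traversal-mode edge set; walk mass at
#' dangling nodes (no outgoing step) is redirected to `r`.  Scores form
#' a probability distribution (sum 1).
#'
#' @param graph An `rpi_graph`.
#' @param seeds Character vector of seed identifiers; seeds absent from
#'   the graph are dropped with a warning.
#' @param config An [rwr_config()].
#' @return Named numeric score vector over all nodes, with attributes
#'   `present_seeds`, `dropped_seeds` and `iterations`.
#' @export
rwr_scores <- function(graph, seeds, config = rwr_config()) {
  stopifnot(inherits(graph, "rpi_graph"))
  seeds <- unique(seeds)
  present <- intersect(seeds, graph$nodes)
  dropped <- setdiff(seeds, graph$nodes)
  if (length(present) == 0L) stop_input("no seed is present in the graph")
  if (length(dropped) > 0L) {
    warning(sprintf("%d seed(s) absent from the graph ignored: %s",
                    length(dropped),
                    paste(utils::head(dropped, 5L), collapse = ", ")),
            call. = FALSE)
  }
  n <- length(graph$nodes)
  alpha <- config$restart_probability
  r <- numeric(n)
  r[match(present, graph$nodes)] <- 1 / length(present)
  A <- walk_adjacency(graph, config$traversal)
  outdeg <- rowSums(A)
  dangling <- outdeg == 0
  Tm <- t(A / pmax(outdeg, 1))  # columns of dangling nodes are zero
  s <- r
  iter <- 0L
  repeat {
    iter <- iter + 1L
    s_new <- (1 - alpha) * (as.vector(Tm %*% s) + sum(s[dangling]) * r) +
      alpha * r
    delta <- sum(abs(s_new - s))
    s <- s_new
    if (delta < config$tolerance || iter >= config$max_iterations) break
  }
  names(s) <- graph$nodes
  attr(s, "present_seeds") <- present
  attr(s, "dropped_seeds") <- dropped
  attr(s, "iterations") <- iter
  s
}

#' Extract the seed-covering subnetwork
#'
#' Ranks nodes by descending RWR score (ties broken lexicographically by
#' identifier) and takes the smallest prefix whose intersection with the
#' present seeds reaches `ceiling(coverage * n_present_seeds)`; the
#' result is the induced multilabel subgraph on that prefix.  Nodes with
#' zero score are ineligible; if the target coverage is unreachable the
#' best achievable prefix is returned with `coverage_warning = TRUE`.
#'
#' @param graph The `rpi_graph` the scores were computed on.
#' @param scores A [rwr_scores()] vector.
#' @param seeds Seed identifiers (the same set given to [rwr_scores()]).
#' @param coverage Target fraction of present seeds to include.
#' @return A `seed_subnetwork`: list with `graph` (induced subgraph),
#'   `member_nodes` (prefix in rank order), `ranking` (data frame of
#'   node, score, is_seed, rank), `coverage_achieved`,
#'   `coverage_target` and `coverage_warning`.
#' @export
extract_subnetwork <- function(graph, scores, seeds, coverage = 0.8) {
  stopifnot(inherits(graph, "rpi_graph"),
            coverage > 0, coverage <= 1)
  present <- intersect(unique(seeds), graph$nodes)
  if (length(present) == 0L) stop_input("no seed is present in the graph")
  ord <- order(-scores, names(scores))
  nodes <- names(scores)[ord]
  sc <- unname(scores)[ord]
  eligible <- sc > 0
  is_seed <- nodes %in% present
  target <- ceiling(coverage * length(present))
  cum <- cumsum(is_seed & eligible)
  reach <- which(cum >= target & eligible)
  warn <- length(reach) == 0L
  k <- if (warn) {
    if (max(cum) == 0L) stop_input("all present seeds have zero score")
    which.max(cum)  # first prefix achieving the best coverage
  } else {
    reach[1L]
  }
  if (warn) {
    warning(sprintf(
      "target coverage %.2f unreachable; achieved %.2f", coverage,
      max(cum) / length(present)), call. = FALSE)
  }
  members <- nodes[seq_len(k)]
  structure(
    list(graph = rpi_subgraph(graph, members),
         member_nodes = members,
         ranking = data.frame(node = nodes, score = sc, is_seed = is_seed,
                              rank = seq_along(nodes),
                              stringsAsFactors = FALSE),
         coverage_achieved = cum[k] / length(present),
         coverage_target = coverage,
         coverage_warning = warn),
    class = "seed_subnetwork")
}

#' @export
print.seed_subnetwork <- function(x, ...) {
  cat(sprintf(
    "seed_subnetwork: %d node(s), seed coverage %.1f%% (target %.0f%%)%s\n",
    length(x$member_nodes), 100 * x$coverage_achieved,
    100 * x$coverage_target,
    if (x$coverage_warning) " [target unreachable]" else ""))
  invisible(x)
}

#' Read a seed list file
#'
#' One identifier per line; `#` comments and blank lines skipped.
#'
#' @param path File path.
#' @return Character vector of identifiers.
#' @export
read_seeds <- function(path) {
  if (!file.exists(path)) stop_input("seed file not found: ", path)
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (length(x) == 0L) stop_input("empty seed file: ", path)
  unique(x)
}
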