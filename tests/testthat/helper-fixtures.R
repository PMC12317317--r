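# Small builders shared across test files.

pairs_df <- function(...) {
  v <- c(...)
  stopifnot(length(v) %% 2 == 0)
  m <- matrix(v, ncol = 2, byrow = TRUE)
  data.frame(a = m[, 1], b = m[, 2], stringsAsFactors = FALSE)
}

mk_graph <- function(phys = NULL, reg = NULL) {
  build_rpi_graph(interaction_table(physical = phys, regulatory = reg))
}

# a random mixed graph for property tests
random_graph <- function(n, seed, p_phys = 0.12, p_reg = 0.06,
                         p_mutual = 0.15) {
  net <- generate_synthetic_network(n, p_phys, p_reg, p_mutual, seed = seed)
  build_rpi_graph(net$table)
}

write_edge_fixture <- function(rows, ext = "tsv", header = NULL) {
  path <- withr::local_tempfile(fileext = paste0(".", ext),
                                .local_envir = parent.frame())
  sep <- if (ext == "csv") "," else "\t"
  lines <- vapply(rows, function(r) paste(r, collapse = sep), "")
  if (!is.null(header)) lines <- c(paste(header, collapse = sep), lines)
  writeLines(lines, path)
  path
}
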