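# Shared infrastructure: typed conditions, delimited-file helpers,
# seeded-RNG plumbing.

stop_input <- function(...) {
  stop(structure(class = c("rpig_input_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_internal <- function(...) {
  stop(structure(class = c("rpig_internal_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# run `expr` under a fixed seed when `seed` is non-NULL, otherwise use the
# current RNG stream
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# derive a child seed (< 2^31) from a base seed and a stream label, so
# independent procedures driven by one global seed get distinct streams
derive_seed <- function(seed, label) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) * 7919L + as.integer(h %% 104729)) %% 2147483647L
}

# field separator by file extension unless given explicitly
guess_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

# header sniffing: a first data row whose fields look like column names
looks_like_header <- function(fields) {
  any(grepl("^(id[0-9]*|node|source|target|regulator|tf|protein|gene|type|interactor)",
            fields, ignore.case = TRUE))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
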