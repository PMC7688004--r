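# Internal helpers shared across modules.

# Split a sequence into single-residue characters.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Stop unless every element of `x` is a non-empty single string.
assert_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    abort(sprintf("`%s` must be a single non-empty string.", what))
  }
  invisible(x)
}

assert_chains_tbl <- function(chains, arg = "chains") {
  if (!is.data.frame(chains) || !all(c("id", "sequence") %in% names(chains))) {
    abort(sprintf("`%s` must be a data frame with columns `id` and `sequence`.", arg))
  }
  if (anyDuplicated(chains$id)) {
    abort(sprintf("`%s` has duplicated chain ids.", arg))
  }
  invisible(chains)
}

# Feature tables carry an `id` (or `complex_id`) key column followed by
# numeric descriptor columns; these helpers convert to/from plain matrices.
feature_matrix <- function(tbl, key = c("id", "complex_id")) {
  key <- intersect(key, names(tbl))[1]
  if (is.na(key)) abort("feature table must have an `id` or `complex_id` column.")
  m <- as.matrix(tbl[setdiff(names(tbl), key)])
  storage.mode(m) <- "double"
  rownames(m) <- tbl[[key]]
  m
}

matrix_to_tbl <- function(m, key_name = "id") {
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  out <- tibble::add_column(out, !!key_name := rownames(m), .before = 1)
  out
}
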