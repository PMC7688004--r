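# Chain-level string kernels and Gram-matrix machinery.

encode_seqs <- function(x) {
  lapply(x, function(s) {
    idx <- match(seq_chars(s), AMINO_ACIDS) - 1L
    if (anyNA(idx)) abort("Sequences must be sanitized to the canonical alphabet first.")
    idx
  })
}

recycle_pair <- function(a, b) {
  if (length(a) == length(b)) return(list(a = a, b = b))
  if (length(a) == 1L) return(list(a = rep(a, length(b)), b = b))
  if (length(b) == 1L) return(list(a = a, b = rep(b, length(a))))
  abort("`a` and `b` must have equal length (or one of length 1).")
}

#' Alignment parameters for the Smith-Waterman and local-alignment kernels
#'
#' Defaults follow common practice for protein local alignment: BLOSUM62
#' scores with affine gap penalties of 11 (opening) and 1 (extension) — a
#' gap of length L costs 11 + (L - 1) — and local-alignment kernel
#' sensitivity beta = 0.1.
#'
#' @param substitution 20 x 20 symmetric substitution matrix.
#' @param gap_open,gap_extend Positive gap penalties, `gap_open >= gap_extend`.
#' @param beta Positive sensitivity parameter of the LA kernel.
#' @return A list of class `alignment_params`.
#' @export
alignment_params <- function(substitution = blosum62(), gap_open = 11,
                             gap_extend = 1, beta = 0.1) {
  if (!(gap_open >= gap_extend && gap_extend > 0)) {
    abort("Need gap_open >= gap_extend > 0.")
  }
  if (beta <= 0) abort("`beta` must be positive.")
  sub <- substitution[AMINO_ACIDS, AMINO_ACIDS]
  if (!isTRUE(all.equal(sub, t(sub)))) abort("`substitution` must be symmetric.")
  structure(list(substitution = sub, gap_open = gap_open,
                 gap_extend = gap_extend, beta = beta),
            class = "alignment_params")
}

#' Smith-Waterman alignment kernel
#'
#' The similarity of two sequences is the optimal affine-gap local-alignment
#' score, i.e. the maximum over all local alignments of the summed
#' substitution scores minus gap costs; the empty alignment scores 0, so the
#' kernel is non-negative. Note that the Gram matrix of this kernel need not
#' be positive semidefinite (see [psd_correct()]).
#'
#' @param a,b Character vectors of sanitized sequences (recycled pairwise).
#' @param params An [alignment_params()].
#' @return Numeric vector of alignment scores.
#' @export
#' @examples
#' sw_kernel("WW", "WW")  # 2 * BLOSUM62(W, W) = 22
sw_kernel <- function(a, b, params = alignment_params()) {
  p <- recycle_pair(a, b)
  sw_kernel_cpp(encode_seqs(p$a), encode_seqs(p$b), params$substitution,
                params$gap_open, params$gap_extend)
}

#' Local-alignment kernel
#'
#' Sums exp(beta * score) over all local alignments of the two sequences,
#' including the empty alignment (which contributes exp(0) = 1), so the
#' kernel value is always >= 1. Computed by a five-state dynamic program in
#' log space; as beta grows, (1 / beta) * log k_LA approaches the
#' Smith-Waterman score.
#'
#' @inheritParams sw_kernel
#' @param beta Overrides `params$beta` when given.
#' @param log Return the log kernel value instead (no overflow).
#' @return Numeric vector of kernel values.
#' @export
la_kernel <- function(a, b, params = alignment_params(), beta = NULL, log = FALSE) {
  if (!is.null(beta)) params$beta <- beta
  if (params$beta <= 0) abort("`beta` must be positive.")
  p <- recycle_pair(a, b)
  lg <- la_kernel_log_cpp(encode_seqs(p$a), encode_seqs(p$b), params$substitution,
                          params$gap_open, params$gap_extend, params$beta)
  if (log) return(lg)
  if (any(lg > log(.Machine$double.xmax))) {
    abort("la_kernel overflows double precision; use `log = TRUE` or a smaller beta.")
  }
  exp(lg)
}

# Number of k-mers u within Hamming distance m of both members of a k-mer
# pair at Hamming distance d, over a 20-letter alphabet. Dynamic program
# over positions tracking mismatches to each member.
mm_pair_counts <- function(k, m, alphabet_size = 20L) {
  counts <- matrix(0, m + 1L, m + 1L)
  counts[1L, 1L] <- 1
  step_agree <- function(cnt) {
    out <- cnt * (alphabet_size - 1)          # u differs from both
    nxt <- matrix(0, m + 1L, m + 1L)
    if (m >= 1) nxt[-1L, -1L] <- out[-(m + 1L), -(m + 1L), drop = FALSE]
    nxt + cnt                                  # u equals the shared letter
  }
  step_differ <- function(cnt) {
    nxt <- matrix(0, m + 1L, m + 1L)
    if (m >= 1) {
      nxt[, -1L] <- nxt[, -1L] + cnt[, -(m + 1L), drop = FALSE]          # u = x
      nxt[-1L, ] <- nxt[-1L, ] + cnt[-(m + 1L), , drop = FALSE]          # u = y
      nxt[-1L, -1L] <- nxt[-1L, -1L] +
        cnt[-(m + 1L), -(m + 1L), drop = FALSE] * (alphabet_size - 2)    # u = other
    }
    nxt
  }
  vapply(0:k, function(d) {
    cnt <- counts
    for (i in seq_len(k - d)) cnt <- step_agree(cnt)
    for (i in seq_len(d)) cnt <- step_differ(cnt)
    sum(cnt)
  }, 0)
}

#' (k, m)-mismatch kernel
#'
#' Inner product of the mismatch-neighbourhood k-mer count profiles of the
#' two sequences: sum over all 20^k k-mers u of N_a(u) * N_b(u), where
#' N_x(u) counts the k-mer positions of x whose k-mer lies within Hamming
#' distance m of u. Computed without materializing the 20^k space, using the
#' fact that a pair of k-mers at Hamming distance d contributes a fixed
#' combinatorial count of shared neighbours. With m = 0 this is the exact
#' k-spectrum kernel.
#'
#' @param a,b Character vectors of sanitized sequences (recycled pairwise).
#' @param k Subsequence length (default 5).
#' @param m Maximum mismatches, `0 <= m < k` (default 3).
#' @return Numeric vector of kernel values.
#' @export
mismatch_kernel <- function(a, b, k = 5L, m = 3L) {
  k <- as.integer(k); m <- as.integer(m)
  if (k < 1L || m < 0L || m >= k) abort("Need k >= 1 and 0 <= m < k.")
  p <- recycle_pair(a, b)
  if (any(nchar(c(p$a, p$b)) < k)) {
    abort(sprintf("All sequences must have at least k = %d residues.", k))
  }
  mismatch_kernel_cpp(encode_seqs(p$a), encode_seqs(p$b), k, mm_pair_counts(k, m))
}

# --- Gram matrices ----------------------------------------------------------

new_gram_matrix <- function(ids, values, kernel_name, params = list(),
                            psd_corrected = FALSE, lambda_min_removed = 0) {
  dimnames(values) <- list(ids, ids)
  if (max(abs(values - t(values))) > 1e-9) abort("Gram matrix must be symmetric.")
  values <- (values + t(values)) / 2
  structure(list(ids = ids, values = values, kernel_name = kernel_name,
                 params = params, psd_corrected = psd_corrected,
                 lambda_min_removed = lambda_min_removed),
            class = "gram_matrix")
}

#' @export
print.gram_matrix <- function(x, ...) {
  cat(sprintf("<gram_matrix> %s kernel, %d x %d%s\n", x$kernel_name,
              nrow(x$values), ncol(x$values),
              if (x$psd_corrected)
                sprintf(", PSD-corrected (lambda_min %.4g removed)", x$lambda_min_removed)
              else ""))
  invisible(x)
}

#' Gram matrix of an arbitrary kernel over a list of items
#'
#' Evaluates `kernel` once per unordered pair.
#'
#' @param items List (or vector) of items; names become the Gram ids.
#' @param kernel Function of two items returning a scalar.
#' @param kernel_name Label stored on the result.
#' @return A `gram_matrix`.
#' @export
gram <- function(items, kernel, kernel_name = "custom") {
  if (length(items) < 1L) abort("Need at least one item.")
  ids <- names(items) %||% as.character(seq_along(items))
  n <- length(items)
  values <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      v <- tryCatch(kernel(items[[i]], items[[j]]),
        error = function(e) abort(sprintf("Kernel failed on pair (%s, %s): %s",
                                          ids[i], ids[j], conditionMessage(e))))
      values[i, j] <- values[j, i] <- v
    }
  }
  new_gram_matrix(ids, values, kernel_name)
}

# Fast path shared by chain_gram() and complex_gram(): full (possibly
# rectangular) kernel matrix between two sequence sets.
kernel_matrix_raw <- function(seqs_a, seqs_b, kernel, params, k, m, symmetric) {
  code <- match(kernel, c("sw", "la", "mismatch"))
  pair_counts <- if (kernel == "mismatch") mm_pair_counts(k, m) else numeric(1)
  if (kernel == "mismatch" && any(nchar(c(seqs_a, seqs_b)) < k)) {
    abort(sprintf("All sequences must have at least k = %d residues.", k))
  }
  gram_cpp(encode_seqs(seqs_a), encode_seqs(seqs_b), symmetric, code - 1L,
           params$substitution, params$gap_open, params$gap_extend,
           params$beta, as.integer(k), pair_counts)
}

#' Chain-level Gram matrix
#'
#' @param chains Tibble with columns `id`, `sequence`.
#' @param kernel `"sw"`, `"la"` or `"mismatch"`.
#' @param params An [alignment_params()] (SW/LA kernels).
#' @param k,m Mismatch-kernel parameters.
#' @param normalize Apply cosine normalization
#'   k(a, b) / sqrt(k(a, a) k(b, b)) (off by default).
#' @return A `gram_matrix` keyed by chain id.
#' @export
chain_gram <- function(chains, kernel = c("sw", "la", "mismatch"),
                       params = alignment_params(), k = 5L, m = 3L,
                       normalize = FALSE) {
  assert_chains_tbl(chains)
  kernel <- match.arg(kernel)
  values <- kernel_matrix_raw(chains$sequence, chains$sequence, kernel,
                              params, k, m, TRUE)
  if (normalize) values <- cosine_normalize(values)
  new_gram_matrix(chains$id, values, kernel,
                  params = list(gap_open = params$gap_open,
                                gap_extend = params$gap_extend,
                                beta = params$beta, k = k, m = m,
                                normalize = normalize))
}

cosine_normalize <- function(values) {
  d <- sqrt(pmax(diag(values), 0))
  d[d == 0] <- 1
  values / outer(d, d)
}

#' Shift a Gram matrix onto the positive-semidefinite cone
#'
#' Alignment-score kernels need not satisfy Mercer's condition; when the
#' smallest eigenvalue lambda_min of the Gram matrix is negative, the matrix
#' is replaced by G - lambda_min * I (a diagonal shift), which makes the
#' spectrum non-negative while leaving off-diagonal similarities untouched.
#' Already-PSD input is returned unchanged, and the operation is idempotent.
#'
#' @param g A `gram_matrix`.
#' @return A `gram_matrix` with `psd_corrected` and `lambda_min_removed` set.
#' @export
psd_correct <- function(g) {
  if (!inherits(g, "gram_matrix")) abort("`g` must be a gram_matrix.")
  if (g$psd_corrected) return(g)
  lambda_min <- min(eigen(g$values, symmetric = TRUE, only.values = TRUE)$values)
  if (lambda_min >= 0) {
    g$psd_corrected <- TRUE
    g$lambda_min_removed <- 0
    return(g)
  }
  g$values <- g$values - diag(lambda_min, nrow(g$values))
  g$psd_corrected <- TRUE
  g$lambda_min_removed <- lambda_min
  g
}

#' Write / read a Gram matrix as tab-delimited text
#'
#' Metadata (kernel name, parameters, PSD flag, removed eigenvalue) is kept
#' in `#`-prefixed comment lines; the body is the id-labelled symmetric
#' matrix. Output is byte-stable for identical input.
#'
#' @param g A `gram_matrix`.
#' @param path File path.
#' @return `write_gram()` returns `path` invisibly; `read_gram()` a
#'   `gram_matrix`.
#' @export
write_gram <- function(g, path) {
  meta <- c(
    sprintf("# kernel_name: %s", g$kernel_name),
    sprintf("# params: %s", jsonlite::toJSON(g$params, auto_unbox = TRUE, digits = NA)),
    sprintf("# psd_corrected: %s", tolower(as.character(g$psd_corrected))),
    sprintf("# lambda_min_removed: %.17g", g$lambda_min_removed)
  )
  body <- c(paste(c("id", g$ids), collapse = "\t"),
            vapply(seq_along(g$ids), function(i) {
              paste(c(g$ids[i], sprintf("%.17g", g$values[i, ])), collapse = "\t")
            }, ""))
  writeLines(c(meta, body), path)
  invisible(path)
}

#' @rdname write_gram
#' @export
read_gram <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- function(key) sub(sprintf("^# %s: ", key), "",
                            grep(sprintf("^# %s:", key), meta_lines, value = TRUE))
  body <- lines[!grepl("^#", lines)]
  header <- strsplit(body[1], "\t")[[1]][-1]
  rows <- lapply(body[-1], function(l) strsplit(l, "\t")[[1]])
  values <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1])))
  new_gram_matrix(header, values, meta("kernel_name"),
                  params = jsonlite::fromJSON(meta("params")),
                  psd_corrected = identical(meta("psd_corrected"), "true"),
                  lambda_min_removed = as.numeric(meta("lambda_min_removed")))
}
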