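# Independent brute-force oracles and fixture builders used across tests.
# The oracles share no code with the package's dynamic programs.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

oracle_blosum <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62[AA20, AA20]
})

# All gapped local alignments of two short strings, as a vector of scores.
# A local alignment is a strictly increasing sequence of aligned residue
# pairs; the gap between consecutive pairs costs open + (L - 1) * ext per
# gapped stretch in each sequence. The empty alignment scores 0.
enumerate_alignment_scores <- function(a, b, sub = oracle_blosum,
                                       open = 11, ext = 1) {
  ach <- strsplit(a, "")[[1]]
  bch <- strsplit(b, "")[[1]]
  n <- length(ach); m <- length(bch)
  gap_cost <- function(L) if (L == 0) 0 else open + (L - 1) * ext
  scores <- 0  # empty alignment
  rec <- function(i, j, acc) {
    scores <<- c(scores, acc)
    if (i < n && j < m) {
      for (ii in (i + 1):n) {
        for (jj in (j + 1):m) {
          rec(ii, jj, acc + sub[ach[ii], bch[jj]] -
                gap_cost(ii - i - 1) - gap_cost(jj - j - 1))
        }
      }
    }
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      rec(i, j, sub[ach[i], bch[j]])
    }
  }
  scores
}

oracle_sw <- function(a, b, ...) max(enumerate_alignment_scores(a, b, ...))

oracle_la <- function(a, b, beta = 0.1, ...) {
  sum(exp(beta * enumerate_alignment_scores(a, b, ...)))
}

# Brute-force (k, m)-mismatch kernel: materializes the full 20^k k-mer
# space and counts neighbourhood co-occurrence. Feasible for k <= 3.
oracle_mismatch <- function(a, b, k, m) {
  code <- function(s) {
    v <- match(strsplit(s, "")[[1]], AA20) - 1L
    n <- length(v) - k + 1L
    sapply(seq_len(n), function(i) v[i:(i + k - 1L)])  # k x n digit matrix
  }
  ka <- code(a); kb <- code(b)
  if (is.null(dim(ka))) ka <- matrix(ka, nrow = k)
  if (is.null(dim(kb))) kb <- matrix(kb, nrow = k)
  # digit matrix of every u in the 20^k space, k x 20^k
  u <- t(as.matrix(expand.grid(rep(list(0:19), k))))
  count_neigh <- function(kmers) {
    # for each u: number of k-mer positions within Hamming distance m
    acc <- matrix(0L, ncol(u), ncol(kmers))
    for (pos in seq_len(k)) {
      acc <- acc + outer(u[pos, ], kmers[pos, ], "!=")
    }
    rowSums(acc <= m)
  }
  sum(count_neigh(ka) * count_neigh(kb))
}

random_protein <- function(len, alphabet = AA20) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

random_chain_tbl <- function(n, len_range = c(40, 60), prefix = "ch") {
  pick_len <- function() {
    if (len_range[1] == len_range[2]) len_range[1]
    else sample(len_range[1]:len_range[2], 1)
  }
  tibble::tibble(
    id = paste0(prefix, seq_len(n)),
    sequence = vapply(seq_len(n), function(i) random_protein(pick_len()), "")
  )
}

# Tiny hand-built dataset: three complexes over five chains.
tiny_dataset <- function(delta_g = c(-10, -8, -12)) {
  chains <- tibble::tibble(
    id = c("A", "B", "C", "D", "E"),
    sequence = c("MKVLAARPGG", "ACDEFGHIKL", "MNPQRSTVWY",
                 "GGGGSSSSAA", "WWYYFFHHKK")
  )
  complexes <- tibble::tibble(
    complex_id = c("C1", "C2", "C3"),
    ligand = list(c("A", "B"), "C", "D"),
    receptor = list("C", c("D", "E"), "E"),
    delta_g = delta_g,
    kd = rep(NA_real_, 3)
  )
  complex_dataset(chains, complexes, provenance = "test fixture")
}
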