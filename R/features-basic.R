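# Per-chain explicit sequence descriptors: amino-acid composition, averaged
# BLOSUM62 columns, averaged PSSM columns, and ProtParam-style
# physicochemical indices.

.pkg_cache <- new.env(parent = emptyenv())

#' The BLOSUM62 substitution matrix over the canonical alphabet
#'
#' The published BLOSUM62 scores (via Biostrings), subset to the 20
#' canonical residues.
#'
#' @return A symmetric 20 x 20 integer matrix.
#' @export
blosum62 <- function() {
  if (is.null(.pkg_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$blosum62 <- e$BLOSUM62[AMINO_ACIDS, AMINO_ACIDS]
  }
  .pkg_cache$blosum62
}

# Count matrix: one row per chain, columns in AMINO_ACIDS order.
aac_counts <- function(sequences) {
  t(vapply(
    sequences,
    function(s) {
      tab <- table(factor(seq_chars(s), levels = AMINO_ACIDS))
      as.numeric(tab)
    },
    numeric(20L)
  ))
}

#' Amino-acid composition features
#'
#' For each chain, the number of times each of the 20 amino acids occurs
#' (raw counts; scaling to unit norm happens downstream in the regression
#' pipeline).
#'
#' @param chains Tibble with columns `id`, `sequence`.
#' @return A tibble: `id` plus 20 count columns named `aac_A` ... `aac_V`.
#' @export
#' @examples
#' feat_aac(tibble::tibble(id = "c1", sequence = "ACDA"))
feat_aac <- function(chains) {
  assert_chains_tbl(chains)
  m <- aac_counts(chains$sequence)
  colnames(m) <- paste0("aac_", AMINO_ACIDS)
  rownames(m) <- chains$id
  matrix_to_tbl(m)
}

#' Averaged substitution-matrix features
#'
#' Each chain is encoded as the mean over its residues of the BLOSUM62
#' column for that residue, capturing which physicochemically similar
#' substitutions the sequence tolerates.
#'
#' @param chains Tibble with columns `id`, `sequence`.
#' @param matrix Substitution matrix (default [blosum62()]); must be a
#'   symmetric 20 x 20 matrix indexed by the canonical residues.
#' @return A tibble: `id` plus 20 columns `blosum_A` ... `blosum_V`.
#' @export
feat_blosum <- function(chains, matrix = blosum62()) {
  assert_chains_tbl(chains)
  if (!isTRUE(all.equal(matrix, t(matrix)))) abort("`matrix` must be symmetric.")
  counts <- aac_counts(chains$sequence)
  lens <- nchar(chains$sequence)
  # mean of per-residue columns == composition-weighted average of columns
  m <- (counts %*% matrix[AMINO_ACIDS, AMINO_ACIDS]) / lens
  colnames(m) <- paste0("blosum_", AMINO_ACIDS)
  rownames(m) <- chains$id
  matrix_to_tbl(m)
}

#' Averaged PSSM profile features
#'
#' Encodes each chain by the columnwise mean of its position-specific
#' scoring matrix (20 log-odds per residue, e.g. from three PSI-BLAST
#' iterations against nr). When no profile is available for a chain and
#' `fallback = "blosum"`, the BLOSUM62 column of each residue stands in for
#' the profile row (making the feature equal [feat_blosum()] for that
#' chain); the substitution is flagged in the `pssm_source` attribute.
#'
#' @param chains Tibble with columns `id`, `sequence`.
#' @param profiles Named list of PSSM tibbles from [read_pssm_ascii()],
#'   keyed by chain id.
#' @param fallback `"blosum"` (default) or `"error"` for chains without a
#'   profile.
#' @return A tibble: `id` plus 20 columns `pssm_A` ... `pssm_V`.
#' @export
feat_pssm <- function(chains, profiles = list(), fallback = c("blosum", "error")) {
  assert_chains_tbl(chains)
  fallback <- match.arg(fallback)
  bl <- blosum62()
  source <- character(nrow(chains))
  rows <- lapply(seq_len(nrow(chains)), function(i) {
    id <- chains$id[i]
    s <- chains$sequence[i]
    prof <- profiles[[id]]
    if (is.null(prof)) {
      if (fallback == "error") abort(sprintf("No PSSM profile for chain '%s'.", id))
      source[i] <<- "blosum62-fallback"
      colMeans(bl[seq_chars(s), , drop = FALSE])
    } else {
      scores <- as.matrix(prof[AMINO_ACIDS])
      if (nrow(scores) != nchar(s)) {
        abort(sprintf("PSSM for chain '%s' has %d rows but the chain has %d residues.",
                      id, nrow(scores), nchar(s)))
      }
      source[i] <- "profile"
      colMeans(scores)
    }
  })
  m <- do.call(rbind, rows)
  colnames(m) <- paste0("pssm_", AMINO_ACIDS)
  rownames(m) <- chains$id
  out <- matrix_to_tbl(m)
  attr(out, "pssm_source") <- setNames(source, chains$id)
  out
}

# --- ProtParam-style physicochemical indices --------------------------------

# Bjellqvist-style pKa values used for the isoelectric point.
PKA_POSITIVE <- c(Nterm = 7.5, K = 10, R = 12, H = 5.98)
PKA_NEGATIVE <- c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9, Y = 10)

AROMATIC_SET <- c("F", "W", "Y")
HELIX_SET <- c("V", "I", "Y", "F", "W", "L")
TURN_SET <- c("N", "P", "G", "S")
SHEET_SET <- c("E", "M", "A", "L")

protein_mw <- function(s) {
  sum(RESIDUE_MASS[seq_chars(s)]) + WATER_MASS
}

instability_index <- function(s) {
  ch <- seq_chars(s)
  n <- length(ch)
  if (n < 2L) return(0)
  (10 / n) * sum(DIWV[cbind(ch[-n], ch[-1])])
}

# Net charge at a given pH from the Henderson-Hasselbalch equation.
peptide_charge <- function(counts_pos, counts_neg, ph) {
  pos <- sum(counts_pos / (1 + 10^(ph - PKA_POSITIVE)))
  neg <- sum(counts_neg / (1 + 10^(PKA_NEGATIVE - ph)))
  pos - neg
}

isoelectric_point <- function(s, tol = 1e-4) {
  ch <- seq_chars(s)
  counts_pos <- c(Nterm = 1, K = sum(ch == "K"), R = sum(ch == "R"), H = sum(ch == "H"))
  counts_neg <- c(Cterm = 1, D = sum(ch == "D"), E = sum(ch == "E"),
                  C = sum(ch == "C"), Y = sum(ch == "Y"))
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (peptide_charge(counts_pos, counts_neg, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' ProtParam-style physicochemical features
#'
#' Seven global physicochemical indices per chain: average molecular weight
#' (Da), aromaticity (fraction of F/W/Y), the Guruprasad instability index,
#' the isoelectric point (bisection on the Henderson-Hasselbalch net charge
#' with Bjellqvist/ExPASy pKa values), and the residue fractions of the
#' conventional helix (VIYFWL), turn (NPGS) and sheet (EMAL) sets.
#'
#' @param chains Tibble with columns `id`, `sequence`.
#' @return A tibble: `id` plus columns `molecular_weight`, `aromaticity`,
#'   `instability_index`, `isoelectric_point`, `helix_fraction`,
#'   `turn_fraction`, `sheet_fraction`.
#' @export
feat_protparam <- function(chains) {
  assert_chains_tbl(chains)
  frac <- function(s, set) {
    ch <- seq_chars(s)
    mean(ch %in% set)
  }
  tibble::tibble(
    id = chains$id,
    molecular_weight = vapply(chains$sequence, protein_mw, 0, USE.NAMES = FALSE),
    aromaticity = vapply(chains$sequence, frac, 0, set = AROMATIC_SET,
                         USE.NAMES = FALSE),
    instability_index = vapply(chains$sequence, instability_index, 0,
                               USE.NAMES = FALSE),
    isoelectric_point = vapply(chains$sequence, isoelectric_point, 0,
                               USE.NAMES = FALSE),
    helix_fraction = vapply(chains$sequence, frac, 0, set = HELIX_SET,
                            USE.NAMES = FALSE),
    turn_fraction = vapply(chains$sequence, frac, 0, set = TURN_SET,
                           USE.NAMES = FALSE),
    sheet_fraction = vapply(chains$sequence, frac, 0, set = SHEET_SET,
                            USE.NAMES = FALSE)
  )
}

#' Compute a named chain descriptor
#'
#' Dispatcher over the five explicit per-chain descriptor families.
#'
#' @param chains Tibble with columns `id`, `sequence`.
#' @param descriptor One of `"aac"`, `"blosum"`, `"pssm"`, `"protparam"`,
#'   `"composite"`.
#' @param ... Passed to the specific featurizer (e.g. `profiles` for
#'   `"pssm"`, `config` for `"composite"`).
#' @return A tibble: `id` plus descriptor columns.
#' @export
chain_features <- function(chains,
                           descriptor = c("aac", "blosum", "pssm",
                                          "protparam", "composite"),
                           ...) {
  descriptor <- match.arg(descriptor)
  switch(descriptor,
    aac = feat_aac(chains),
    blosum = feat_blosum(chains, ...),
    pssm = feat_pssm(chains, ...),
    protparam = feat_protparam(chains),
    composite = feat_composite(chains, ...)
  )
}

#' Names of the available chain descriptors
#' @return Character vector.
#' @export
descriptor_names <- function() c("aac", "blosum", "pssm", "protparam", "composite")

#' Write a feature table as delimited text
#'
#' @param features Tibble with an `id`/`complex_id` key column and numeric
#'   descriptor columns.
#' @param path Output path (tab-delimited, header row of element names).
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  readr::write_tsv(features, path)
  invisible(path)
}
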