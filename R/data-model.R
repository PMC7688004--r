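# Domain types, file readers/writers, and thermodynamic conversions.

AMINO_ACIDS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Gas constant in kcal / (mol K).
GAS_CONSTANT_KCAL <- 1.9872e-3

#' Sanitize a protein sequence to the canonical 20-letter alphabet
#'
#' Sequences are upper-cased, whitespace and gap characters are dropped, and
#' non-canonical residue codes are resolved: the ambiguity codes B, Z and the
#' rare residues U (selenocysteine) and O (pyrrolysine) map to their closest
#' canonical residues (D, E, C, K); anything else, including X, is replaced
#' by alanine with a warning. Every downstream featurizer and kernel assumes
#' the canonical alphabet.
#'
#' @param x Character vector of amino-acid sequences.
#' @return Character vector of sanitized sequences.
#' @export
#' @examples
#' sanitize_sequence("mkvX")
sanitize_sequence <- function(x) {
  if (!is.character(x)) abort("`x` must be a character vector.")
  x <- toupper(gsub("[\\s\\-\\.\\*]", "", x, perl = TRUE))
  x <- chartr("BZUO", "DECK", x)
  bad <- gsub(sprintf("[%s]", paste(AMINO_ACIDS, collapse = "")), "", x)
  if (any(nzchar(bad))) {
    letters_seen <- sort(unique(seq_chars(paste(bad, collapse = ""))))
    warn(sprintf(
      "Non-canonical residue(s) %s replaced by 'A'.",
      paste(letters_seen, collapse = ", ")
    ))
    for (ch in letters_seen) x <- gsub(ch, "A", x, fixed = TRUE)
  }
  x
}

#' Read protein chains from a FASTA file
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return A tibble with columns `id` and `sequence`, in file order.
#'   Sequences are upper-cased and sanitized to the canonical alphabet
#'   (see [sanitize_sequence()]).
#' @export
read_fasta <- function(path) {
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(sprintf("'%s' is not readable as FASTA: %s", path, conditionMessage(e)))
  )
  if (length(set) == 0L) abort(sprintf("'%s' contains no FASTA records.", path))
  seqs <- as.character(set)
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(seqs))) {
    abort(sprintf("FASTA record(s) with empty sequence: %s",
                  paste(ids[!nzchar(seqs)], collapse = ", ")))
  }
  tibble::tibble(id = ids, sequence = sanitize_sequence(unname(seqs)))
}

#' Write protein chains to a FASTA file
#'
#' Output is byte-stable for identical input.
#'
#' @param chains Tibble with columns `id`, `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(chains, path) {
  assert_chains_tbl(chains)
  set <- Biostrings::BStringSet(setNames(chains$sequence, chains$id))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Assemble a complex dataset from chains and a complex table
#'
#' A complex dataset pairs a chain table with a table of ligand/receptor
#' complexes and optional affinity labels. The binding free energy
#' `delta_g` is in kcal/mol (the affinity benchmark this layout mirrors
#' reports delta G in the range -18.58 to -4.29; the units are taken to be
#' kcal/mol) and `kd` is the dissociation constant in molar units.
#'
#' @param chains Tibble with columns `id`, `sequence`.
#' @param complexes Tibble with columns `complex_id`, `ligand` and
#'   `receptor` (list-columns of chain ids), and optionally `delta_g`, `kd`.
#' @param provenance Free-text metadata string.
#' @return An object of class `complex_dataset`.
#' @export
complex_dataset <- function(chains, complexes, provenance = "") {
  assert_chains_tbl(chains)
  if (!all(c("complex_id", "ligand", "receptor") %in% names(complexes))) {
    abort("`complexes` needs columns `complex_id`, `ligand`, `receptor`.")
  }
  if (anyDuplicated(complexes$complex_id)) {
    abort(sprintf("Duplicate complex id(s): %s",
                  paste(unique(complexes$complex_id[duplicated(complexes$complex_id)]),
                        collapse = ", ")))
  }
  if (!("delta_g" %in% names(complexes))) complexes$delta_g <- NA_real_
  if (!("kd" %in% names(complexes))) complexes$kd <- NA_real_
  referenced <- unique(unlist(c(complexes$ligand, complexes$receptor)))
  missing <- setdiff(referenced, chains$id)
  if (length(missing)) {
    abort(sprintf("Complex table references unknown chain id(s): %s",
                  paste(missing, collapse = ", ")))
  }
  n_lig <- lengths(complexes$ligand)
  n_rec <- lengths(complexes$receptor)
  if (any(n_lig < 1L) || any(n_rec < 1L)) {
    abort("Every complex needs at least one ligand and one receptor chain.")
  }
  both <- !is.na(complexes$delta_g) & !is.na(complexes$kd)
  if (any(both)) {
    implied <- delta_g_to_kd(complexes$delta_g[both])
    off <- abs(implied - complexes$kd[both]) / implied > 0.01
    if (any(off)) {
      warn(sprintf(
        "delta_g and kd disagree by more than 1%% for complex(es): %s",
        paste(complexes$complex_id[both][off], collapse = ", ")
      ))
    }
  }
  structure(
    list(chains = tibble::as_tibble(chains),
         complexes = tibble::as_tibble(complexes),
         provenance = provenance),
    class = "complex_dataset"
  )
}

#' @export
print.complex_dataset <- function(x, ...) {
  n_lab <- sum(!is.na(x$complexes$delta_g))
  cat(sprintf("<complex_dataset> %d complexes, %d chains, %d with affinity labels\n",
              nrow(x$complexes), nrow(x$chains), n_lab))
  if (nzchar(x$provenance)) cat("provenance:", x$provenance, "\n")
  invisible(x)
}

#' Number of complexes in a dataset
#' @param dataset A `complex_dataset`.
#' @return Integer count.
#' @export
n_complexes <- function(dataset) nrow(dataset$complexes)

# Guard used by cross-validation entry points.
assert_cv_ready <- function(dataset, min_n = 2L) {
  if (!inherits(dataset, "complex_dataset")) abort("`dataset` must be a complex_dataset.")
  if (n_complexes(dataset) < min_n) {
    abort(sprintf("Cross-validation needs at least %d complexes; got %d.",
                  min_n, n_complexes(dataset)))
  }
  if (anyNA(dataset$complexes$delta_g)) {
    abort("All complexes must carry a delta_g label for cross-validation.")
  }
  invisible(dataset)
}

#' Read a complex table and resolve it against a chain set
#'
#' The table is comma-delimited with columns `complex_id`, `ligand_chains`,
#' `receptor_chains`, `delta_g`, `kd`; the chain columns hold
#' semicolon-separated chain ids, and `kd` may be empty.
#'
#' @param path Path to the CSV table.
#' @param chains Tibble of chains (see [read_fasta()]).
#' @return A [complex_dataset()].
#' @export
read_complex_table <- function(path, chains) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      complex_id = readr::col_character(),
      ligand_chains = readr::col_character(),
      receptor_chains = readr::col_character(),
      delta_g = readr::col_double(),
      kd = readr::col_double()
    )
  )
  complexes <- tibble::tibble(
    complex_id = raw$complex_id,
    ligand = strsplit(raw$ligand_chains, ";", fixed = TRUE),
    receptor = strsplit(raw$receptor_chains, ";", fixed = TRUE),
    delta_g = raw$delta_g,
    kd = raw$kd
  )
  complex_dataset(chains, complexes, provenance = sprintf("read from %s", path))
}

#' Write the complex table of a dataset
#'
#' @param dataset A `complex_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_complex_table <- function(dataset, path) {
  tbl <- tibble::tibble(
    complex_id = dataset$complexes$complex_id,
    ligand_chains = vapply(dataset$complexes$ligand, paste, "", collapse = ";"),
    receptor_chains = vapply(dataset$complexes$receptor, paste, "", collapse = ";"),
    delta_g = dataset$complexes$delta_g,
    kd = dataset$complexes$kd
  )
  readr::write_csv(tbl, path)
  invisible(path)
}

#' Read a PSI-BLAST ASCII PSSM profile
#'
#' Parses the layout produced by `psiblast -out_ascii_pssm`: header and
#' footer lines are skipped; each residue row contributes its 20 log-odds
#' scores (the first score block).
#'
#' @param path Path to the ASCII PSSM file.
#' @param chain_id Optional chain id to attach.
#' @return A tibble with columns `position`, `residue`, and one column per
#'   canonical amino acid, attribute `chain_id`.
#' @export
read_pssm_ascii <- function(path, chain_id = NULL) {
  lines <- readLines(path)
  positions <- integer()
  residues <- character()
  rows <- list()
  for (i in seq_along(lines)) {
    tokens <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tokens) < 3L) next
    if (!grepl("^[0-9]+$", tokens[1])) next
    if (!grepl("^[A-Za-z]$", tokens[2])) next
    scores <- suppressWarnings(as.numeric(tokens[-(1:2)]))
    if (length(scores) < 20L || anyNA(scores[1:20])) {
      abort(sprintf("Malformed PSSM row at line %d of '%s': expected 20 score columns.",
                    i, path))
    }
    positions <- c(positions, as.integer(tokens[1]))
    residues <- c(residues, toupper(tokens[2]))
    rows[[length(rows) + 1L]] <- scores[1:20]
  }
  if (!length(rows)) abort(sprintf("No PSSM rows found in '%s'.", path))
  m <- do.call(rbind, rows)
  out <- tibble::as_tibble(setNames(as.data.frame(m), AMINO_ACIDS))
  out <- tibble::add_column(out, position = positions, residue = residues,
                            .before = 1)
  attr(out, "chain_id") <- chain_id
  out
}

#' Convert binding free energy to a dissociation constant
#'
#' Uses the thermodynamic relation Kd = exp(delta G / (R T)) with
#' R = 1.9872e-3 kcal/(mol K). The default temperature is the standard
#' 298.15 K; more negative delta G means tighter binding (smaller Kd).
#'
#' @param delta_g Binding free energy, kcal/mol.
#' @param temperature Absolute temperature, K (default 298.15).
#' @return Dissociation constant(s), molar.
#' @export
#' @examples
#' delta_g_to_kd(-9.556)
delta_g_to_kd <- function(delta_g, temperature = 298.15) {
  if (any(!is.finite(delta_g))) abort("`delta_g` must be finite.")
  if (any(temperature <= 0)) abort("`temperature` must be positive.")
  exp(delta_g / (GAS_CONSTANT_KCAL * temperature))
}

#' @rdname delta_g_to_kd
#' @param kd Dissociation constant(s), molar; must be positive.
#' @export
kd_to_delta_g <- function(kd, temperature = 298.15) {
  if (any(!is.finite(kd)) || any(kd <= 0)) abort("`kd` must be finite and positive.")
  if (any(temperature <= 0)) abort("`temperature` must be positive.")
  GAS_CONSTANT_KCAL * temperature * log(kd)
}

# Pull one complex out of a dataset as a self-contained record:
# list(complex_id, ligand = chains tibble, receptor = chains tibble,
#      delta_g, kd).
#' Extract one complex with resolved chain sequences
#' @param dataset A `complex_dataset`.
#' @param id Complex id.
#' @return A list with `complex_id`, chain tibbles `ligand` and `receptor`,
#'   `delta_g` and `kd`.
#' @export
extract_complex <- function(dataset, id) {
  i <- match(id, dataset$complexes$complex_id)
  if (is.na(i)) abort(sprintf("No complex '%s' in dataset.", id))
  row <- dataset$complexes[i, ]
  pick <- function(ids) dataset$chains[match(ids, dataset$chains$id), ]
  list(
    complex_id = row$complex_id,
    ligand = pick(row$ligand[[1]]),
    receptor = pick(row$receptor[[1]]),
    delta_g = row$delta_g,
    kd = row$kd
  )
}
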