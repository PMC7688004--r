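# Lifting chain-level features and kernels to complex level, plus the
# feature-scaling pipeline used by the regression models.

#' Complex-level feature representation
#'
#' Each complex is represented by the chain-averaged ligand descriptor
#' followed by the chain-averaged receptor descriptor: the ligand block is
#' the mean of the chain feature vectors over all ligand chains, likewise
#' for the receptor, and the two blocks are concatenated ligand-first. The
#' representation is invariant to chain order within a side but changes if
#' ligand and receptor are swapped.
#'
#' @param dataset A `complex_dataset`.
#' @param features Chain feature tibble (`id` + numeric columns) covering
#'   every chain referenced by the dataset, e.g. from [chain_features()].
#' @return A tibble: `complex_id` plus `lig_*` and `rec_*` columns (twice
#'   the chain descriptor dimension).
#' @export
complex_features <- function(dataset, features) {
  if (!inherits(dataset, "complex_dataset")) abort("`dataset` must be a complex_dataset.")
  fm <- feature_matrix(features, key = "id")
  missing <- setdiff(unique(unlist(c(dataset$complexes$ligand, dataset$complexes$receptor))),
                     rownames(fm))
  if (length(missing)) {
    abort(sprintf("`features` lacks chain(s): %s", paste(missing, collapse = ", ")))
  }
  side_mean <- function(ids) colMeans(fm[ids, , drop = FALSE])
  m <- t(mapply(function(l, r) c(side_mean(l), side_mean(r)),
                dataset$complexes$ligand, dataset$complexes$receptor))
  colnames(m) <- c(paste0("lig_", colnames(fm)), paste0("rec_", colnames(fm)))
  rownames(m) <- dataset$complexes$complex_id
  matrix_to_tbl(m, key_name = "complex_id")
}

# Mean chain-pair kernel between two complexes given a chain-level kernel
# matrix `cm` (rows/cols indexed by chain id).
complex_pair_value <- function(cm, lig1, rec1, lig2, rec2,
                               pairing = c("all", "matched")) {
  pairing <- match.arg(pairing)
  if (pairing == "all") {
    mean(cm[c(lig1, rec1), c(lig2, rec2), drop = FALSE])
  } else {
    (mean(cm[lig1, lig2, drop = FALSE]) + mean(cm[rec1, rec2, drop = FALSE])) / 2
  }
}

#' Complex-level kernel between two complexes
#'
#' Averages the chain-level kernel over chain pairs drawn from the two
#' complexes. With `pairing = "all"` (default) every chain of one complex is
#' paired with every chain of the other (ligand and receptor pooled), i.e.
#' K(c, c') = mean over q in c, q' in c' of k(q, q'). With
#' `pairing = "matched"` only ligand-ligand and receptor-receptor pairs are
#' averaged.
#'
#' @param c1,c2 Complex records from [extract_complex()] (or lists with
#'   chain tibbles `ligand` and `receptor`).
#' @param kernel,params,k,m Chain kernel selection as in [chain_gram()].
#' @param pairing `"all"` or `"matched"`.
#' @return A single kernel value.
#' @export
complex_kernel <- function(c1, c2, kernel = c("sw", "la", "mismatch"),
                           params = alignment_params(), k = 5L, m = 3L,
                           pairing = c("all", "matched")) {
  kernel <- match.arg(kernel)
  pairing <- match.arg(pairing)
  chains1 <- rbind(c1$ligand, c1$receptor)
  chains2 <- rbind(c2$ligand, c2$receptor)
  cm <- kernel_matrix_raw(chains1$sequence, chains2$sequence, kernel,
                          params, k, m, FALSE)
  dimnames(cm) <- list(seq_len(nrow(chains1)), seq_len(nrow(chains2)))
  n1 <- nrow(c1$ligand); n2 <- nrow(c2$ligand)
  complex_pair_value(cm,
                     lig1 = as.character(seq_len(n1)),
                     rec1 = as.character(n1 + seq_len(nrow(c1$receptor))),
                     lig2 = as.character(seq_len(n2)),
                     rec2 = as.character(n2 + seq_len(nrow(c2$receptor))),
                     pairing = pairing)
}

#' Complex-level Gram matrix
#'
#' Computes the chain-level Gram over the dataset's chains once, then lifts
#' it to complexes by chain-pair averaging (see [complex_kernel()]).
#'
#' @param dataset A `complex_dataset`.
#' @inheritParams complex_kernel
#' @param normalize Cosine-normalize the chain-level kernel first.
#' @return A `gram_matrix` keyed by complex id.
#' @export
complex_gram <- function(dataset, kernel = c("sw", "la", "mismatch"),
                         params = alignment_params(), k = 5L, m = 3L,
                         pairing = c("all", "matched"), normalize = FALSE) {
  if (!inherits(dataset, "complex_dataset")) abort("`dataset` must be a complex_dataset.")
  kernel <- match.arg(kernel)
  pairing <- match.arg(pairing)
  cg <- chain_gram(dataset$chains, kernel, params, k, m, normalize)
  cm <- cg$values
  cx <- dataset$complexes
  n <- nrow(cx)
  values <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      values[i, j] <- values[j, i] <- complex_pair_value(
        cm, cx$ligand[[i]], cx$receptor[[i]], cx$ligand[[j]], cx$receptor[[j]],
        pairing = pairing)
    }
  }
  new_gram_matrix(cx$complex_id, values, kernel,
                  params = c(cg$params, list(pairing = pairing, level = "complex")))
}

#' Cross-kernel matrix between query and training complexes
#'
#' Computes the rectangular complex-level kernel matrix K(query, train) by
#' chain-pair averaging, one row per query complex and one column per
#' training complex, for prediction with a precomputed-Gram model. Cross
#' terms are used as-is: the PSD diagonal shift applied to the training
#' Gram does not alter them.
#'
#' @param train,query `complex_dataset` objects.
#' @inheritParams complex_gram
#' @return A numeric matrix with query complex ids as rows and training
#'   complex ids as columns.
#' @export
complex_cross_gram <- function(query, train, kernel = c("sw", "la", "mismatch"),
                               params = alignment_params(), k = 5L, m = 3L,
                               pairing = c("all", "matched"),
                               normalize = FALSE) {
  kernel <- match.arg(kernel)
  pairing <- match.arg(pairing)
  qc <- query$chains; tc <- train$chains
  cm <- kernel_matrix_raw(qc$sequence, tc$sequence, kernel, params, k, m, FALSE)
  if (normalize) {
    self_q <- kernel_matrix_raw(qc$sequence, qc$sequence, kernel, params, k, m, TRUE)
    self_t <- kernel_matrix_raw(tc$sequence, tc$sequence, kernel, params, k, m, TRUE)
    dq <- sqrt(pmax(diag(self_q), 0)); dq[dq == 0] <- 1
    dt <- sqrt(pmax(diag(self_t), 0)); dt[dt == 0] <- 1
    cm <- cm / outer(dq, dt)
  }
  dimnames(cm) <- list(qc$id, tc$id)
  qx <- query$complexes; tx <- train$complexes
  out <- matrix(0, nrow(qx), nrow(tx),
                dimnames = list(qx$complex_id, tx$complex_id))
  for (i in seq_len(nrow(qx))) {
    for (j in seq_len(nrow(tx))) {
      out[i, j] <- complex_pair_value(cm, qx$ligand[[i]], qx$receptor[[i]],
                                      tx$ligand[[j]], tx$receptor[[j]],
                                      pairing = pairing)
    }
  }
  out
}

# --- feature scaling --------------------------------------------------------

#' Fit the feature scaler on training rows
#'
#' The regression pipeline first scales every sample (row) to unit L2 norm,
#' then standardizes each feature (column) to zero mean and unit standard
#' deviation using statistics of the training rows only. `apply_scaler()`
#' replays both steps on held-out rows with the stored training statistics;
#' it refuses to run before fitting. Zero-norm rows skip the unit-norm step;
#' constant columns get a unit divisor.
#'
#' @param x Feature tibble (`id`/`complex_id` + numeric columns) or numeric
#'   matrix of training rows.
#' @param unit_norm Apply the per-sample unit-norm step before column
#'   standardization (default `TRUE`; set `FALSE` for a purely affine
#'   pipeline).
#' @return An object of class `feature_scaler`.
#' @export
fit_scaler <- function(x, unit_norm = TRUE) {
  m <- if (is.data.frame(x)) feature_matrix(x) else as.matrix(x)
  if (unit_norm) m <- unit_norm_rows(m)
  center <- colMeans(m)
  scale <- apply(m, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  structure(list(center = center, scale = scale, fitted = TRUE,
                 unit_norm = unit_norm, p = ncol(m)), class = "feature_scaler")
}

unit_norm_rows <- function(m) {
  norms <- sqrt(rowSums(m^2))
  norms[norms == 0] <- 1
  m / norms
}

#' @rdname fit_scaler
#' @param scaler A fitted `feature_scaler`.
#' @return `apply_scaler()` returns an object of the same shape as `x` with
#'   scaled numeric columns.
#' @export
apply_scaler <- function(scaler, x) {
  if (!inherits(scaler, "feature_scaler") || !isTRUE(scaler$fitted)) {
    abort("`scaler` must be a fitted feature_scaler (see fit_scaler()).")
  }
  is_df <- is.data.frame(x)
  m <- if (is_df) feature_matrix(x) else as.matrix(x)
  if (ncol(m) != scaler$p) {
    abort(sprintf("Scaler was fitted on %d features; got %d.", scaler$p, ncol(m)))
  }
  if (isTRUE(scaler$unit_norm)) m <- unit_norm_rows(m)
  m <- sweep(sweep(m, 2, scaler$center), 2, scaler$scale, "/")
  if (!is_df) return(m)
  key <- intersect(c("id", "complex_id"), names(x))[1]
  out <- matrix_to_tbl(m, key_name = key)
  names(out) <- c(key, setdiff(names(x), key))
  out
}
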