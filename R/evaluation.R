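# Leave-one-complex-out cross-validation, metrics, the sequence-homology
# nearest-neighbour baseline, and the descriptor-by-model sweep driver.

#' Root mean squared error
#' @param y_true,y_pred Equal-length numeric vectors.
#' @return A single non-negative number.
#' @export
rmse <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || !length(y_true)) {
    abort("`y_true` and `y_pred` must have equal, positive length.")
  }
  sqrt(mean((y_true - y_pred)^2))
}

#' Pearson correlation with a two-sided p-value
#'
#' The p-value comes from the t statistic r * sqrt((n - 2) / (1 - r^2))
#' with n - 2 degrees of freedom. When either vector has zero variance the
#' correlation is undefined and reported as `NA` (never silently 0), with a
#' warning.
#'
#' @param y_true,y_pred Equal-length numeric vectors (n >= 3 for the
#'   p-value).
#' @return A list with elements `r` and `p_value`.
#' @export
pearson <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) abort("Vectors must have equal length.")
  n <- length(y_true)
  if (sd(y_true) == 0 || sd(y_pred) == 0) {
    warn("Zero variance: Pearson correlation undefined, reported as NA.")
    return(list(r = NA_real_, p_value = NA_real_))
  }
  r <- cor(y_true, y_pred)
  p <- if (n >= 3) {
    if (abs(r) >= 1) 0 else {
      t_stat <- r * sqrt((n - 2) / (1 - r^2))
      2 * pt(-abs(t_stat), df = n - 2)
    }
  } else NA_real_
  list(r = r, p_value = p)
}

new_loco_result <- function(predictions, meta) {
  agg <- pearson(predictions$observed, predictions$predicted)
  structure(list(
    predictions = predictions,
    n = nrow(predictions),
    rmse = rmse(predictions$observed, predictions$predicted),
    pearson_r = agg$r,
    p_value = agg$p_value,
    meta = meta
  ), class = "loco_result")
}

#' @export
print.loco_result <- function(x, ...) {
  cat(sprintf("<loco_result> %s | n = %d, RMSE = %.4g, Pearson r = %.4g (p = %.3g)\n",
              paste(unlist(x$meta[c("representation", "descriptor", "kernel", "model")]),
                    collapse = "/"),
              x$n, x$rmse, x$pearson_r, x$p_value))
  invisible(x)
}

#' @describeIn loco_cv Per-complex predictions as a tibble.
#' @param x A `loco_result`.
#' @param ... Unused.
#' @export
tidy.loco_result <- function(x, ...) x$predictions

#' @describeIn loco_cv One-row aggregate summary (n, RMSE, Pearson r,
#'   p-value and pipeline metadata).
#' @export
glance.loco_result <- function(x, ...) {
  tibble::tibble(
    representation = x$meta$representation %||% NA_character_,
    descriptor = x$meta$descriptor %||% NA_character_,
    kernel = x$meta$kernel %||% NA_character_,
    model = x$meta$model %||% NA_character_,
    n = x$n, rmse = x$rmse, pearson_r = x$pearson_r, p_value = x$p_value
  )
}

#' Leave-one-complex-out cross-validation
#'
#' For every complex in the dataset, fits the full pipeline — feature
#' scaling, grid-search hyperparameter selection and the regression model —
#' on the remaining complexes and predicts the held-out one. Chain features
#' and chain/complex kernels are computed once (they involve no training
#' statistics); everything that learns from affinities is refit per fold, so
#' no held-out information leaks into training.
#'
#' @param dataset A labelled `complex_dataset` (n >= 3).
#' @param representation `"features"` (explicit descriptors + any model
#'   kind), `"kernel"` (precomputed complex Gram + SVR), or `"baseline"`
#'   (sequence-homology nearest neighbour).
#' @param descriptor Chain descriptor for `"features"` (see
#'   [chain_features()]).
#' @param features Optional precomputed chain feature tibble (overrides
#'   `descriptor`).
#' @param profiles,composite Passed to the descriptor where relevant.
#' @param kernel,params,k,m,pairing,normalize Kernel selection for
#'   `"kernel"`/`"baseline"` (see [complex_gram()]; the baseline always uses
#'   the Smith-Waterman kernel).
#' @param model Model kind for `"features"` (`"kernel"` implies
#'   `"svr_precomputed"`).
#' @param grid Hyperparameter grid (default [default_grid()]).
#' @param inner_folds,seed Inner CV folds and seed for model selection.
#' @param scaling Feature-scaling pipeline (see [select_hyperparameters()]).
#' @return A `loco_result`: per-complex predictions plus aggregate RMSE,
#'   Pearson r and p-value.
#' @export
loco_cv <- function(dataset,
                    representation = c("features", "kernel", "baseline"),
                    descriptor = "aac", features = NULL, profiles = list(),
                    composite = composite_config(),
                    kernel = c("sw", "la", "mismatch"),
                    params = alignment_params(), k = 5L, m = 3L,
                    pairing = c("all", "matched"), normalize = FALSE,
                    model = "olsr", grid = NULL, inner_folds = 5L, seed = 1L,
                    scaling = c("unit_standardize", "standardize", "none")) {
  representation <- match.arg(representation)
  kernel <- match.arg(kernel)
  pairing <- match.arg(pairing)
  scaling <- match.arg(scaling)
  assert_cv_ready(dataset, min_n = 3L)
  cx <- dataset$complexes
  y <- cx$delta_g
  n <- nrow(cx)

  if (representation == "features") {
    if (is.null(features)) {
      features <- switch(descriptor,
        pssm = feat_pssm(dataset$chains, profiles = profiles),
        composite = feat_composite(dataset$chains, config = composite),
        chain_features(dataset$chains, descriptor))
    }
    xtbl <- complex_features(dataset, features)
    xm <- feature_matrix(xtbl, key = "complex_id")
    meta <- list(representation = "features", descriptor = descriptor,
                 model = model, scaling = scaling)
  } else {
    used_kernel <- if (representation == "baseline") "sw" else kernel
    G <- complex_gram(dataset, used_kernel, params, k, m, pairing, normalize)
    model <- if (representation == "baseline") "homology" else "svr_precomputed"
    meta <- list(representation = representation, kernel = used_kernel,
                 model = model, pairing = pairing)
  }

  preds <- numeric(n)
  for (i in seq_len(n)) {
    id <- cx$complex_id[i]
    preds[i] <- tryCatch({
      tr <- setdiff(seq_len(n), i)
      if (representation == "features") {
        fit <- fit_affinity_model(xm[tr, , drop = FALSE], y[tr], model = model,
                                  grid = grid, seed = seed,
                                  inner_folds = inner_folds, scaling = scaling)
        predict(fit, xm[i, , drop = FALSE])
      } else if (representation == "kernel") {
        g_tr <- new_gram_matrix(cx$complex_id[tr], G$values[tr, tr, drop = FALSE],
                                G$kernel_name, params = G$params)
        fit <- fit_affinity_model(y = y[tr], model = "svr_precomputed",
                                  grid = grid, gram = g_tr, seed = seed,
                                  inner_folds = inner_folds)
        predict(fit, G$values[i, tr, drop = FALSE])
      } else {
        sims <- G$values[i, tr]
        y[tr][which.max(sims)]
      }
    }, error = function(e) {
      abort(sprintf("LOCO fold for complex '%s' failed: %s", id,
                    conditionMessage(e)))
    })
  }

  new_loco_result(
    tibble::tibble(complex_id = cx$complex_id, observed = y, predicted = preds,
                   abs_error = abs(y - preds)),
    meta
  )
}

#' Sequence-homology nearest-neighbour baseline
#'
#' Predicts the binding free energy of a query complex as the affinity of
#' its closest homolog in the training set, where similarity between two
#' complexes is the chain-pair-averaged Smith-Waterman alignment score
#' (BLOSUM62, gap penalties 11/1). Ties break in dataset order.
#'
#' @param train A labelled `complex_dataset`.
#' @param query A complex record from [extract_complex()] (ligand/receptor
#'   chain tibbles).
#' @param params An [alignment_params()].
#' @param pairing Chain-pair averaging mode (see [complex_kernel()]).
#' @return A list: `delta_g` (the prediction), `complex_id` of the best
#'   match, and its `similarity`.
#' @export
homology_baseline <- function(train, query, params = alignment_params(),
                              pairing = c("all", "matched")) {
  pairing <- match.arg(pairing)
  if (!inherits(train, "complex_dataset")) abort("`train` must be a complex_dataset.")
  if (n_complexes(train) < 1L) abort("Training set is empty.")
  sims <- vapply(train$complexes$complex_id, function(id) {
    complex_kernel(query, extract_complex(train, id), kernel = "sw",
                   params = params, pairing = pairing)
  }, 0)
  best <- which.max(sims)
  list(delta_g = train$complexes$delta_g[best],
       complex_id = train$complexes$complex_id[best],
       similarity = unname(sims[best]))
}

#' Cumulative histogram of absolute prediction errors
#'
#' @param result A `loco_result` (or a tibble with an `abs_error` column).
#' @param bin_edges Increasing numeric vector of error thresholds
#'   (kcal/mol).
#' @return A tibble with columns `edge` and `cum_fraction`, the fraction of
#'   complexes with absolute error <= edge.
#' @export
error_histogram <- function(result, bin_edges = seq(0.5, 5, by = 0.5)) {
  errs <- if (inherits(result, "loco_result")) result$predictions$abs_error
          else result$abs_error
  if (is.null(errs) || !length(errs)) abort("`result` carries no absolute errors.")
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    abort("`bin_edges` must be strictly increasing.")
  }
  tibble::tibble(edge = bin_edges,
                 cum_fraction = vapply(bin_edges, function(e) mean(errs <= e), 0))
}

#' Descriptor-by-model evaluation sweep
#'
#' Runs leave-one-complex-out cross-validation for every combination of the
#' five explicit descriptors with the three regression model families, plus
#' each string kernel with precomputed-Gram SVR (kernel representations are
#' not applicable to OLSR/RFR), and returns one combined results table.
#'
#' @param dataset A labelled `complex_dataset`.
#' @param descriptors Explicit descriptors to include.
#' @param models Model families for explicit descriptors: `"olsr"`, `"rfr"`,
#'   `"svr"` (RBF support vector regression).
#' @param kernels String kernels to include with precomputed-Gram SVR.
#' @param grids Optional named list of grid overrides keyed by model family
#'   (`olsr`, `rfr`, `svr`, `svr_precomputed`).
#' @param profiles,composite,params,k,m,pairing,normalize,inner_folds,seed,scaling
#'   Passed through to [loco_cv()].
#' @return A tibble with one row per configuration: representation,
#'   descriptor/kernel, model, n, RMSE, Pearson r, p-value.
#' @export
affinity_sweep <- function(dataset,
                           descriptors = c("aac", "blosum", "pssm",
                                           "protparam", "composite"),
                           models = c("olsr", "rfr", "svr"),
                           kernels = c("sw", "la", "mismatch"),
                           grids = list(), profiles = list(),
                           composite = composite_config(),
                           params = alignment_params(), k = 5L, m = 3L,
                           pairing = "all", normalize = FALSE,
                           inner_folds = 5L, seed = 1L,
                           scaling = "unit_standardize") {
  model_kind <- c(olsr = "olsr", rfr = "rfr", svr = "svr_rbf")
  rows <- list()
  for (d in descriptors) {
    features <- switch(d,
      pssm = feat_pssm(dataset$chains, profiles = profiles),
      composite = feat_composite(dataset$chains, config = composite),
      chain_features(dataset$chains, d))
    for (mo in models) {
      res <- loco_cv(dataset, "features", descriptor = d, features = features,
                     model = model_kind[[mo]], grid = grids[[mo]],
                     inner_folds = inner_folds, seed = seed, scaling = scaling)
      rows[[length(rows) + 1L]] <- glance(res)
    }
  }
  for (kn in kernels) {
    res <- loco_cv(dataset, "kernel", kernel = kn, params = params, k = k,
                   m = m, pairing = pairing, normalize = normalize,
                   grid = grids[["svr_precomputed"]],
                   inner_folds = inner_folds, seed = seed)
    rows[[length(rows) + 1L]] <- glance(res)
  }
  dplyr::bind_rows(rows)
}

#' Write evaluation results as CSV
#'
#' @param result A `loco_result`.
#' @param per_complex_path,aggregate_path Output CSV paths.
#' @return The paths, invisibly.
#' @export
write_evaluation <- function(result, per_complex_path, aggregate_path) {
  readr::write_csv(tidy(result), per_complex_path)
  readr::write_csv(glance(result), aggregate_path)
  invisible(c(per_complex_path, aggregate_path))
}
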