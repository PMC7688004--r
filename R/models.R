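# Regression learners behind a single train/predict contract: ordinary
# least squares (minimum-norm), eps-insensitive support vector regression
# (linear, RBF, or precomputed Gram) and random-forest regression, with
# seeded grid-search model selection by inner k-fold cross-validation.

MODEL_KINDS <- c("olsr", "svr_linear", "svr_rbf", "svr_precomputed", "rfr")
MODEL_FILE_VERSION <- "seqaffinity-model-1"

#' Default hyperparameter grids
#'
#' Standard logarithmic grids: C in 10^(-2..3), epsilon in
#' \{0.001, 0.01, 0.1, 0.5, 1\}, gamma in 10^(-4..0) plus the
#' reciprocal-dimension heuristic, 100/200/500 trees and minimum split
#' sizes 2/5/10. All are configurable per call.
#'
#' @param model One of `r paste0('"', MODEL_KINDS, '"', collapse = ", ")`.
#' @param n_features Feature count, used for the 1/d gamma heuristic.
#' @return Named list of grid vectors (empty for `"olsr"`).
#' @export
default_grid <- function(model = MODEL_KINDS, n_features = NULL) {
  model <- match.arg(model)
  C <- c(0.01, 0.1, 1, 10, 100, 1000)
  eps <- c(0.001, 0.01, 0.1, 0.5, 1)
  gamma <- c(1e-4, 1e-3, 1e-2, 1e-1, 1)
  if (!is.null(n_features)) gamma <- sort(unique(c(gamma, 1 / n_features)))
  switch(model,
    olsr = list(),
    svr_linear = list(C = C, epsilon = eps),
    svr_rbf = list(C = C, epsilon = eps, gamma = gamma),
    svr_precomputed = list(C = C, epsilon = eps),
    rfr = list(n_trees = c(100, 200, 500), min_samples_split = c(2, 5, 10))
  )
}

# Deterministic fold assignment.
fold_assign <- function(n, folds, seed) {
  set.seed(seed)
  sample(rep(seq_len(folds), length.out = n))
}

as_model_matrix <- function(x) {
  if (inherits(x, "gram_matrix")) abort("Pass gram_matrix input via `gram = `.")
  m <- if (is.data.frame(x)) feature_matrix(x) else as.matrix(x)
  storage.mode(m) <- "double"
  m
}

# --- individual learners ----------------------------------------------------

fit_olsr <- function(x, y) {
  xbar <- colMeans(x)
  ybar <- mean(y)
  xc <- sweep(x, 2, xbar)
  sv <- svd(xc)
  tol <- max(dim(x)) * .Machine$double.eps * max(sv$d, 0)
  pos <- sv$d > tol
  w <- if (any(pos)) {
    sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], y - ybar)) / sv$d[pos])
  } else {
    matrix(0, ncol(x), 1)
  }
  list(w = drop(w), b = ybar - sum(xbar * drop(w)))
}

# An eps-SVR whose training targets all sit inside the epsilon tube has no
# support vectors; the regression function is then the constant centre of
# the tube, which kernlab reports as an error rather than a model.
fit_svr <- function(expr, y) {
  tryCatch(expr, error = function(e) {
    if (grepl("No Support Vectors", conditionMessage(e))) {
      structure(list(constant = mean(y)), class = "constant_predictor")
    } else {
      abort(conditionMessage(e))
    }
  })
}

fit_one <- function(kind, x, y, gram_train, hp, seed) {
  switch(kind,
    olsr = fit_olsr(x, y),
    svr_linear = fit_svr(kernlab::ksvm(x, y, scaled = FALSE, type = "eps-svr",
                                       kernel = "vanilladot", kpar = list(),
                                       C = hp$C, epsilon = hp$epsilon), y),
    svr_rbf = fit_svr(kernlab::ksvm(x, y, scaled = FALSE, type = "eps-svr",
                                    kernel = "rbfdot", kpar = list(sigma = hp$gamma),
                                    C = hp$C, epsilon = hp$epsilon), y),
    svr_precomputed = fit_svr(
      kernlab::ksvm(kernlab::as.kernelMatrix(gram_train), y,
                    type = "eps-svr", C = hp$C, epsilon = hp$epsilon), y),
    rfr = ranger::ranger(
      x = as.data.frame(x), y = y,
      num.trees = hp$n_trees, min.node.size = hp$min_samples_split,
      seed = seed, num.threads = 1
    )
  )
}

predict_one <- function(kind, fit, x, gram_cross) {
  if (inherits(fit, "constant_predictor")) {
    n <- if (is.null(x)) nrow(gram_cross) else nrow(x)
    return(rep(fit$constant, n))
  }
  switch(kind,
    olsr = drop(x %*% fit$w) + fit$b,
    svr_linear = ,
    svr_rbf = drop(kernlab::predict(fit, x)),
    svr_precomputed = {
      sv <- kernlab::SVindex(fit)
      drop(kernlab::predict(
        fit, kernlab::as.kernelMatrix(gram_cross[, sv, drop = FALSE])))
    },
    rfr = predict(fit, data = as.data.frame(x), num.threads = 1)$predictions
  )
}

#' Grid-search model selection by inner cross-validation
#'
#' Evaluates every grid setting with seeded k-fold cross-validation on the
#' supplied (training) data and returns the setting minimizing mean RMSE;
#' ties break in grid order. A singleton grid is returned without
#' cross-validating. For feature inputs the per-fold pipeline refits the
#' scaler on each inner training split, so no held-out statistics leak.
#'
#' @param x Feature matrix/tibble (feature kinds) or `NULL`.
#' @param y Numeric response (binding free energy, kcal/mol).
#' @param model Model kind, see [default_grid()].
#' @param grid Named list of hyperparameter value vectors.
#' @param gram Training `gram_matrix` for `"svr_precomputed"`.
#' @param folds Inner fold count (default 5; reduced with a warning when it
#'   exceeds the sample count).
#' @param seed Integer seed controlling fold assignment and forest growth.
#' @param scaling Feature-scaling pipeline applied inside each inner fold
#'   (feature kinds only): `"unit_standardize"` (per-sample unit norm, then
#'   column standardization; the default), `"standardize"` (columns only) or
#'   `"none"`.
#' @return List with elements `hyperparameters` and `inner_rmse`.
#' @export
select_hyperparameters <- function(x, y, model, grid = NULL, gram = NULL,
                                   folds = 5L, seed = 1L,
                                   scaling = c("unit_standardize", "standardize", "none")) {
  scaling <- match.arg(scaling)
  model <- match.arg(model, MODEL_KINDS)
  if (is.null(grid)) {
    nf <- if (!is.null(x)) ncol(as_model_matrix(x)) else NULL
    grid <- default_grid(model, n_features = nf)
  }
  if (!length(grid)) return(list(hyperparameters = list(), inner_rmse = NA_real_))
  settings <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (nrow(settings) == 1L) {
    return(list(hyperparameters = as.list(settings[1L, , drop = FALSE]),
                inner_rmse = NA_real_))
  }
  n <- length(y)
  if (folds > n) {
    warn(sprintf("Reducing inner folds from %d to %d (training size).", folds, n))
    folds <- n
  }
  fold_id <- fold_assign(n, folds, seed)
  xm <- if (!is.null(x)) as_model_matrix(x) else NULL
  G <- if (!is.null(gram)) gram$values else NULL
  score <- vapply(seq_len(nrow(settings)), function(s) {
    hp <- as.list(settings[s, , drop = FALSE])
    errs <- unlist(lapply(seq_len(folds), function(f) {
      tr <- fold_id != f; te <- !tr
      if (!any(te) || sum(tr) < 2) return(numeric(0))
      if (model == "svr_precomputed") {
        g_tr <- new_gram_matrix(as.character(which(tr)), G[tr, tr, drop = FALSE], "inner")
        g_tr <- psd_correct(g_tr)
        fit <- fit_one(model, NULL, y[tr], g_tr$values, hp, seed)
        pred <- predict_one(model, fit, NULL, G[te, tr, drop = FALSE])
      } else {
        xtr <- xm[tr, , drop = FALSE]; xte <- xm[te, , drop = FALSE]
        if (scaling != "none") {
          sc <- fit_scaler(xtr, unit_norm = scaling == "unit_standardize")
          xtr <- apply_scaler(sc, xtr); xte <- apply_scaler(sc, xte)
        }
        fit <- fit_one(model, xtr, y[tr], NULL, hp, seed)
        pred <- predict_one(model, fit, xte, NULL)
      }
      pred - y[te]
    }))
    sqrt(mean(errs^2))
  }, 0)
  best <- which.min(score)
  list(hyperparameters = as.list(settings[best, , drop = FALSE]),
       inner_rmse = score[best])
}

#' Fit an affinity regression model
#'
#' Trains one of the supported learners on complex-level features or a
#' precomputed (PSD-corrected) complex Gram matrix. Hyperparameters are
#' chosen by [select_hyperparameters()] unless the grid is a single setting.
#' Feature inputs are passed through the unit-norm + standardization scaler,
#' fitted here on the training rows and stored with the model.
#'
#' @param x Feature tibble (`complex_id`/`id` + numeric columns) or numeric
#'   matrix; `NULL` for `"svr_precomputed"`.
#' @param y Numeric binding free energies (kcal/mol), aligned with rows.
#' @param model Model kind.
#' @param grid Hyperparameter grid (default [default_grid()]).
#' @param gram Training `gram_matrix` (required for `"svr_precomputed"`;
#'   PSD-corrected automatically if needed).
#' @param seed Integer seed (fold assignment, random forest).
#' @param inner_folds Inner CV folds for the grid search.
#' @param scaling Feature-scaling pipeline (see [select_hyperparameters()]).
#' @return An object of class `affinity_model`.
#' @export
fit_affinity_model <- function(x = NULL, y, model = MODEL_KINDS, grid = NULL,
                               gram = NULL, seed = 1L, inner_folds = 5L,
                               scaling = c("unit_standardize", "standardize", "none")) {
  model <- match.arg(model)
  scaling <- match.arg(scaling)
  if (length(y) < 2L) abort("Need at least 2 training examples.")
  if (model == "svr_precomputed") {
    if (is.null(gram)) abort("`svr_precomputed` needs a training `gram`.")
    if (!inherits(gram, "gram_matrix")) abort("`gram` must be a gram_matrix.")
    if (nrow(gram$values) != length(y)) abort("`gram` and `y` are misaligned.")
    if (!gram$psd_corrected) gram <- psd_correct(gram)
    sel <- select_hyperparameters(NULL, y, model, grid, gram = gram,
                                  folds = inner_folds, seed = seed)
    fit <- fit_one(model, NULL, y, gram$values, sel$hyperparameters, seed)
    return(structure(list(model_kind = model, fit = fit, scaler = NULL,
                          hyperparameters = sel$hyperparameters,
                          inner_rmse = sel$inner_rmse,
                          train_ids = gram$ids, feature_names = NULL,
                          n_train = length(y), version = MODEL_FILE_VERSION),
                     class = "affinity_model"))
  }
  xm <- as_model_matrix(x)
  if (nrow(xm) != length(y)) abort("`x` and `y` are misaligned.")
  sel <- select_hyperparameters(xm, y, model, grid, folds = inner_folds,
                                seed = seed, scaling = scaling)
  scaler <- if (scaling != "none") {
    fit_scaler(xm, unit_norm = scaling == "unit_standardize")
  }
  xs <- if (!is.null(scaler)) apply_scaler(scaler, xm) else xm
  fit <- fit_one(model, xs, y, NULL, sel$hyperparameters, seed)
  structure(list(model_kind = model, fit = fit, scaler = scaler,
                 hyperparameters = sel$hyperparameters,
                 inner_rmse = sel$inner_rmse,
                 train_ids = rownames(xm), feature_names = colnames(xm),
                 n_train = length(y), version = MODEL_FILE_VERSION),
            class = "affinity_model")
}

#' Predict binding free energy
#'
#' @param object An `affinity_model`.
#' @param newdata Feature tibble/matrix matching the training features, or —
#'   for `"svr_precomputed"` — the cross-kernel matrix with one row per new
#'   complex and one column per training complex (training-fold order).
#' @param ... Unused.
#' @return Numeric vector of predicted delta G (kcal/mol).
#' @export
predict.affinity_model <- function(object, newdata, ...) {
  if (object$model_kind == "svr_precomputed") {
    g <- if (inherits(newdata, "gram_matrix")) newdata$values else as.matrix(newdata)
    if (ncol(g) != object$n_train) {
      abort(sprintf("Cross-kernel matrix must have %d columns (training complexes).",
                    object$n_train))
    }
    return(predict_one(object$model_kind, object$fit, NULL, g))
  }
  xm <- as_model_matrix(newdata)
  if (!is.null(object$feature_names) && ncol(xm) != length(object$feature_names)) {
    abort(sprintf("Model expects %d features; got %d.",
                  length(object$feature_names), ncol(xm)))
  }
  if (!is.null(object$scaler)) xm <- apply_scaler(object$scaler, xm)
  predict_one(object$model_kind, object$fit, xm, NULL)
}

#' @export
print.affinity_model <- function(x, ...) {
  hp <- if (length(x$hyperparameters)) {
    paste(names(x$hyperparameters), unlist(x$hyperparameters),
          sep = " = ", collapse = ", ")
  } else "none"
  cat(sprintf("<affinity_model> %s, %d training complexes\n  hyperparameters: %s\n",
              x$model_kind, x$n_train, hp))
  invisible(x)
}

#' @describeIn fit_affinity_model Coefficients of linear kinds (weights and
#'   intercept) or the selected hyperparameters otherwise, as a tibble.
#' @param x An `affinity_model` (for `tidy()`/`glance()`).
#' @param ... Unused.
#' @export
tidy.affinity_model <- function(x, ...) {
  if (x$model_kind == "olsr") {
    return(tibble::tibble(term = c("(Intercept)", x$feature_names %||%
                                     paste0("x", seq_along(x$fit$w))),
                          estimate = c(x$fit$b, x$fit$w)))
  }
  if (x$model_kind == "svr_linear") {
    sv <- kernlab::xmatrix(x$fit)
    if (is.list(sv)) sv <- sv[[1]]
    w <- drop(crossprod(sv, unlist(kernlab::coef(x$fit))))
    return(tibble::tibble(term = c("(Intercept)", x$feature_names %||%
                                     paste0("x", seq_along(w))),
                          estimate = c(-kernlab::b(x$fit), w)))
  }
  tibble::tibble(term = names(x$hyperparameters),
                 estimate = as.numeric(unlist(x$hyperparameters)))
}

#' @describeIn fit_affinity_model One-row model summary.
#' @export
glance.affinity_model <- function(x, ...) {
  tibble::tibble(model_kind = x$model_kind, n_train = x$n_train,
                 inner_rmse = x$inner_rmse,
                 hyperparameters = paste(names(x$hyperparameters),
                                         unlist(x$hyperparameters),
                                         sep = "=", collapse = ";"))
}

#' Save / load a fitted model
#'
#' Models are serialized with a version tag; loading refuses a mismatched
#' version.
#'
#' @param model An `affinity_model` (or the homology-baseline model of
#'   [fit_homology_model()]).
#' @param path File path.
#' @return `save_affinity_model()` returns `path` invisibly;
#'   `load_affinity_model()` the model.
#' @export
save_affinity_model <- function(model, path) {
  saveRDS(list(version = MODEL_FILE_VERSION, model = model), path)
  invisible(path)
}

#' @rdname save_affinity_model
#' @export
load_affinity_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$version, MODEL_FILE_VERSION)) {
    abort(sprintf("Model file version '%s' does not match expected '%s'.",
                  obj$version %||% "<missing>", MODEL_FILE_VERSION))
  }
  obj$model
}
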