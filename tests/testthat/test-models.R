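make_linear_toy <- function(n = 30, d = 5, sd_noise = 0, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * d), n, d, dimnames = list(NULL, paste0("f", 1:d)))
  w <- rnorm(d)
  b <- -11
  y <- drop(x %*% w) + b + rnorm(n, 0, sd_noise)
  list(x = x, y = y, w = w, b = b)
}

test_that("OLSR recovers the generating weights on noise-free linear data", {
  toy <- make_linear_toy()
  m <- fit_affinity_model(toy$x, toy$y, "olsr", scaling = "none")
  expect_equal(unname(m$fit$w), toy$w, tolerance = 1e-8)
  expect_equal(m$fit$b, toy$b, tolerance = 1e-8)
  expect_equal(unname(predict(m, toy$x)), toy$y, tolerance = 1e-8)
  co <- tidy(m)
  expect_equal(co$estimate[co$term == "(Intercept)"], toy$b, tolerance = 1e-8)
})

test_that("OLSR uses the minimum-norm solution on wide designs", {
  set.seed(4)
  x <- matrix(rnorm(5 * 20), 5, 20)
  y <- rnorm(5)
  m <- fit_affinity_model(x, y, "olsr", scaling = "none")
  # training residuals vanish in the interpolating regime
  expect_equal(unname(predict(m, x)), y, tolerance = 1e-8)
  # the weight vector lies in the row space of the centered design
  xc <- sweep(x, 2, colMeans(x))
  proj <- crossprod(xc, solve(tcrossprod(xc) + 1e-12 * diag(5),
                              xc %*% m$fit$w))
  expect_equal(unname(drop(proj)), unname(m$fit$w), tolerance = 1e-6)
})

test_that("all model kinds reproduce a constant response on training rows", {
  set.seed(6)
  x <- matrix(rnorm(12 * 3), 12, 3)
  y <- rep(-9, 12)
  for (kind in c("olsr", "svr_linear", "svr_rbf", "rfr")) {
    grid <- switch(kind,
      svr_linear = list(C = 10, epsilon = 0.01),
      svr_rbf = list(C = 10, epsilon = 0.01, gamma = 0.1),
      rfr = list(n_trees = 50, min_samples_split = 2),
      NULL)
    m <- fit_affinity_model(x, y, kind, grid = grid, seed = 3)
    expect_equal(unname(predict(m, x)), y, tolerance = 0.011)
  }
})

test_that("random forest training is reproducible under a fixed seed", {
  toy <- make_linear_toy(40, 4, sd_noise = 0.5, seed = 9)
  grid <- list(n_trees = 100, min_samples_split = 2)
  m1 <- fit_affinity_model(toy$x, toy$y, "rfr", grid = grid, seed = 11)
  m2 <- fit_affinity_model(toy$x, toy$y, "rfr", grid = grid, seed = 11)
  expect_identical(predict(m1, toy$x), predict(m2, toy$x))
})

test_that("SVR training predictions respect the epsilon tube on easy data", {
  toy <- make_linear_toy(25, 3, sd_noise = 0, seed = 12)
  m <- fit_affinity_model(toy$x, toy$y, "svr_linear",
                          grid = list(C = 1000, epsilon = 0.05),
                          scaling = "standardize")
  expect_lt(max(abs(predict(m, toy$x) - toy$y)), 0.06)
})

test_that("precomputed-kernel SVR reproduces its dual expansion", {
  set.seed(15)
  x <- matrix(rnorm(8 * 3), 8, 3)
  K <- tcrossprod(x)  # linear kernel, PSD by construction
  y <- drop(x %*% c(1, -2, 0.5)) - 10
  g <- seqaffinity:::new_gram_matrix(as.character(1:8), K, "linear-toy")
  m <- fit_affinity_model(y = y, model = "svr_precomputed",
                          grid = list(C = 100, epsilon = 0.01), gram = g)
  pred <- predict(m, K)
  # dual expansion sum_i alpha_i K(x_i, x) + b evaluated by hand
  alpha <- rep(0, 8)
  alpha[kernlab::SVindex(m$fit)] <- unlist(kernlab::coef(m$fit))
  manual <- drop(K %*% alpha) - kernlab::b(m$fit)
  expect_equal(unname(pred), unname(manual), tolerance = 1e-8)
  # a training point reproduces its fitted value
  expect_equal(pred[3], predict(m, K[3, , drop = FALSE]), tolerance = 1e-10)
  # dimension guard
  expect_error(predict(m, K[, 1:5]), "columns")
})

test_that("non-PSD Gram input to precomputed SVR is corrected before fitting", {
  g <- seqaffinity:::new_gram_matrix(c("a", "b", "c"),
                                     matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3),
                                     "indefinite")
  expect_false(g$psd_corrected)
  m <- fit_affinity_model(y = c(-8, -9, -10), model = "svr_precomputed",
                          grid = list(C = 1, epsilon = 0.1), gram = g)
  expect_s3_class(m, "affinity_model")
})

test_that("grid search returns singleton grids untouched and is deterministic", {
  toy <- make_linear_toy(20, 3, sd_noise = 0.3, seed = 21)
  sel <- select_hyperparameters(toy$x, toy$y, "svr_linear",
                                grid = list(C = 7, epsilon = 0.25))
  expect_equal(sel$hyperparameters$C, 7)
  expect_equal(sel$hyperparameters$epsilon, 0.25)
  expect_true(is.na(sel$inner_rmse))

  grid <- list(C = c(0.01, 100), epsilon = c(0.01, 0.5))
  s1 <- select_hyperparameters(toy$x, toy$y, "svr_linear", grid, seed = 5)
  s2 <- select_hyperparameters(toy$x, toy$y, "svr_linear", grid, seed = 5)
  expect_identical(s1, s2)
})

test_that("grid search finds the near-interpolating setting on a noise-free toy", {
  toy <- make_linear_toy(30, 3, sd_noise = 0, seed = 23)
  grid <- list(C = c(1e-4, 1000), epsilon = c(1e-3))
  sel <- select_hyperparameters(toy$x, toy$y, "svr_linear", grid,
                                scaling = "standardize", seed = 2)
  expect_equal(sel$hyperparameters$C, 1000)
  expect_lt(sel$inner_rmse, 0.05)
})

test_that("inner fold count is reduced with a warning on tiny training sets", {
  toy <- make_linear_toy(4, 2, seed = 25)
  expect_warning(
    select_hyperparameters(toy$x, toy$y, "svr_linear",
                           grid = list(C = c(1, 10), epsilon = 0.1),
                           folds = 10),
    "Reducing inner folds"
  )
})

test_that("models survive a save/load round trip bit-identically", {
  toy <- make_linear_toy(20, 4, sd_noise = 0.2, seed = 31)
  m <- fit_affinity_model(toy$x, toy$y, "olsr")
  path <- withr::local_tempfile(fileext = ".rds")
  save_affinity_model(m, path)
  back <- load_affinity_model(path)
  expect_identical(predict(back, toy$x), predict(m, toy$x))
  # version guard
  corrupt <- readRDS(path)
  corrupt$version <- "other-0"
  saveRDS(corrupt, path)
  expect_error(load_affinity_model(path), "version")
})

test_that("prediction refuses mismatched feature dimensionality", {
  toy <- make_linear_toy(15, 4)
  m <- fit_affinity_model(toy$x, toy$y, "olsr")
  expect_error(predict(m, toy$x[, 1:2]), "features")
  # duplicate rows give identical predictions
  two <- predict(m, toy$x[c(3, 3), ])
  expect_equal(two[1], two[2])
})
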