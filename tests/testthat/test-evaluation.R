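test_that("RMSE and Pearson match hand-computed closed forms", {
  expect_equal(rmse(c(1, 2, 3), c(2, 2, 2)), sqrt(2 / 3))
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  p <- pearson(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(p$r, 1)
  expect_equal(p$p_value, 0)
  p <- pearson(c(1, 2, 3), -c(1, 2, 3))
  expect_equal(p$r, -1)
  # p-value from the t transform, checked against the survival function
  y1 <- c(1, 2, 3, 5, 4, 6, 8, 7)
  y2 <- c(1.2, 1.8, 3.4, 4.2, 4.9, 5.6, 7.3, 8.1)
  p <- pearson(y1, y2)
  r <- cor(y1, y2)
  t_stat <- r * sqrt(6 / (1 - r^2))
  expect_equal(p$p_value, 2 * pt(t_stat, df = 6, lower.tail = FALSE))
  expect_equal(p$p_value, cor.test(y1, y2)$p.value, tolerance = 1e-12)
})

test_that("zero-variance inputs yield NA correlation with a warning", {
  expect_warning(p <- pearson(c(2, 2, 2), c(1, 2, 3)), "Zero variance")
  expect_true(is.na(p$r))
  expect_true(is.na(p$p_value))
})

test_that("LOCO produces exactly one prediction per complex", {
  sim <- simulate_affinity_dataset(synthetic_spec(n_complexes = 5, seed = 3))
  res <- loco_cv(sim$dataset, "features", descriptor = "aac", model = "olsr",
                 scaling = "standardize")
  expect_equal(nrow(res$predictions), 5)
  expect_setequal(res$predictions$complex_id,
                  sim$dataset$complexes$complex_id)
  expect_equal(res$predictions$abs_error,
               abs(res$predictions$observed - res$predictions$predicted))
  # recomputing aggregates from the per-complex records reproduces them
  expect_equal(res$rmse, rmse(res$predictions$observed, res$predictions$predicted))
  agg <- pearson(res$predictions$observed, res$predictions$predicted)
  expect_equal(res$pearson_r, agg$r)
  expect_equal(res$p_value, agg$p_value)
})

test_that("noise-free linear data is recovered exactly through LOCO", {
  # low-dimensional descriptor so every fold's design affinely spans the
  # feature support and interpolation is forced
  sim <- simulate_affinity_dataset(
    synthetic_spec(n_complexes = 20, descriptor = "protparam", seed = 5))
  res <- loco_cv(sim$dataset, "features", descriptor = "protparam",
                 model = "olsr", scaling = "standardize")
  expect_lt(res$rmse, 1e-6)
  expect_gt(res$pearson_r, 0.999)
})

test_that("constant responses give zero RMSE and undefined correlation", {
  ds <- tiny_dataset(delta_g = c(-9, -9, -9))
  expect_warning(
    res <- loco_cv(ds, "features", descriptor = "aac", model = "olsr"),
    "Zero variance"
  )
  expect_lt(res$rmse, 1e-9)
  expect_true(is.na(res$pearson_r))
})

test_that("LOCO with a mean predictor matches the closed-form leave-one-out error", {
  ds <- tiny_dataset(delta_g = c(-10, -7, -13))
  n <- 3
  # an all-zero feature column makes OLSR the training-mean predictor
  zero_features <- tibble::tibble(id = ds$chains$id, flat = 0)
  res <- loco_cv(ds, "features", features = zero_features, model = "olsr",
                 scaling = "none")
  y <- ds$complexes$delta_g
  loo_mean <- vapply(seq_len(n), function(i) mean(y[-i]), 0)
  expect_equal(res$predictions$predicted, loo_mean, tolerance = 1e-10)
  expect_equal(res$rmse, sqrt(mean((y - loo_mean)^2)), tolerance = 1e-10)
})

test_that("homology baseline returns the affinity of the closest homolog", {
  sim <- simulate_affinity_dataset(
    synthetic_spec(n_complexes = 6, affinity = "similarity", seed = 7))
  ds <- sim$dataset
  # querying a training complex returns its own label (self-similarity wins)
  q <- extract_complex(ds, "CPX003")
  out <- homology_baseline(ds, q)
  expect_equal(out$complex_id, "CPX003")
  expect_equal(out$delta_g, ds$complexes$delta_g[3])
  # a single-complex training set answers with its label regardless of query
  one <- complex_dataset(ds$chains, ds$complexes[2, ])
  expect_equal(homology_baseline(one, q)$delta_g, ds$complexes$delta_g[2])
})

test_that("homology baseline picks the exact-match complex over a random one", {
  set.seed(19)
  match_chains <- random_chain_tbl(2, c(40, 40), prefix = "m")
  other_chains <- random_chain_tbl(2, c(40, 40), prefix = "o")
  chains <- rbind(match_chains, other_chains)
  train <- complex_dataset(chains, tibble::tibble(
    complex_id = c("match", "random"),
    ligand = list("m1", "o1"), receptor = list("m2", "o2"),
    delta_g = c(-12, -6), kd = c(NA_real_, NA_real_)
  ))
  query <- list(complex_id = "q", ligand = match_chains[1, ],
                receptor = match_chains[2, ], delta_g = NA_real_, kd = NA_real_)
  out <- homology_baseline(train, query)
  expect_equal(out$complex_id, "match")
  expect_equal(out$delta_g, -12)
  # decision agrees with explicitly computed complex-level similarities
  sim_match <- complex_kernel(query, extract_complex(train, "match"), "sw")
  sim_random <- complex_kernel(query, extract_complex(train, "random"), "sw")
  expect_gt(sim_match, sim_random)
})

test_that("error histogram accumulates fractions over sorted edges", {
  preds <- tibble::tibble(abs_error = c(1, 2, 3))
  h <- error_histogram(preds, c(1.5, 2.5))
  expect_equal(h$cum_fraction, c(1 / 3, 2 / 3))
  all_zero <- tibble::tibble(abs_error = rep(0, 4))
  expect_equal(error_histogram(all_zero, 1.5)$cum_fraction, 1)
  expect_error(error_histogram(preds, c(2, 1)), "increasing")
  set.seed(41)
  random <- tibble::tibble(abs_error = runif(50, 0, 5))
  expect_true(all(diff(error_histogram(random, seq(0.5, 5, 0.5))$cum_fraction) >= 0))
})

test_that("kernel-representation LOCO runs end to end with precomputed SVR", {
  sim <- simulate_affinity_dataset(
    synthetic_spec(n_complexes = 8, chain_length = 30,
                   chains_per_side = c(1, 1), seed = 9))
  res <- loco_cv(sim$dataset, "kernel", kernel = "mismatch", k = 3, m = 1,
                 grid = list(C = 10, epsilon = 0.1), seed = 2)
  expect_equal(res$n, 8)
  expect_equal(res$meta$model, "svr_precomputed")
  expect_true(all(is.finite(res$predictions$predicted)))
})

test_that("tidy and glance expose per-complex and aggregate views", {
  ds <- tiny_dataset()
  res <- loco_cv(ds, "baseline")
  expect_s3_class(tidy(res), "tbl_df")
  g <- glance(res)
  expect_equal(g$n, 3)
  expect_equal(g$model, "homology")
  expect_equal(g$rmse, res$rmse)
})

test_that("evaluation results round-trip through CSV files", {
  ds <- tiny_dataset()
  res <- loco_cv(ds, "baseline")
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_evaluation(res, p1, p2)
  per <- readr::read_csv(p1, show_col_types = FALSE)
  expect_equal(per$predicted, res$predictions$predicted)
  agg <- readr::read_csv(p2, show_col_types = FALSE)
  expect_equal(agg$rmse, res$rmse)
})
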