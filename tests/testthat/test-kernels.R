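test_that("Smith-Waterman kernel matches hand-derived scores", {
  # two aligned W-W pairs at BLOSUM62(W, W) = 11 each
  expect_equal(sw_kernel("WW", "WW"), 22)
  # unrelated residues with no positive pair score give the empty alignment
  expect_equal(sw_kernel("A", "D"), 0)
  expect_gte(sw_kernel("MKV", "QQQ"), 0)
})

test_that("SW and LA kernels equal the alignment-enumeration oracle", {
  set.seed(101)
  for (rep in 1:25) {
    a <- random_protein(sample(2:6, 1))
    b <- random_protein(sample(2:6, 1))
    scores <- enumerate_alignment_scores(a, b)
    expect_equal(sw_kernel(a, b), max(scores))
    expect_equal(la_kernel(a, b), sum(exp(0.1 * scores)),
                 tolerance = 1e-9)
    expect_equal(la_kernel(a, b, beta = 0.5), sum(exp(0.5 * scores)),
                 tolerance = 1e-9)
  }
})

test_that("kernels are symmetric in their arguments", {
  set.seed(55)
  for (rep in 1:10) {
    a <- random_protein(sample(3:12, 1))
    b <- random_protein(sample(3:12, 1))
    expect_equal(sw_kernel(a, b), sw_kernel(b, a))
    expect_equal(la_kernel(a, b), la_kernel(b, a))
    expect_equal(mismatch_kernel(a, b, 2, 1), mismatch_kernel(b, a, 2, 1))
  }
})

test_that("la_kernel includes the empty alignment and grows with beta", {
  # alignments of "A" vs "A": empty and the single A-A match (score 4)
  expect_equal(la_kernel("A", "A"), 1 + exp(0.4), tolerance = 1e-12)
  set.seed(77)
  for (rep in 1:5) {
    a <- random_protein(6); b <- random_protein(6)
    expect_gte(la_kernel(a, b), 1)
    # once the best (positive) alignment dominates the sum, the kernel
    # grows with beta
    if (sw_kernel(a, b) > 0) {
      expect_gte(la_kernel(a, b, beta = 8, log = TRUE),
                 la_kernel(a, b, beta = 4, log = TRUE))
    }
  }
})

test_that("scaled log LA kernel approaches the SW score at large beta", {
  set.seed(99)
  for (rep in 1:10) {
    a <- random_protein(sample(3:6, 1))
    b <- random_protein(sample(3:6, 1))
    approx_sw <- la_kernel(a, b, beta = 20, log = TRUE) / 20
    expect_lt(abs(approx_sw - sw_kernel(a, b)), 0.5)
  }
})

test_that("log-space evaluation avoids overflow where linear space cannot", {
  s <- strrep("W", 40)
  expect_error(la_kernel(s, s, beta = 20), "overflow")
  lg <- la_kernel(s, s, beta = 20, log = TRUE)
  expect_true(is.finite(lg))
  expect_gte(lg / 20, sw_kernel(s, s) - 0.5)
})

test_that("mismatch kernel equals brute-force neighbourhood counting", {
  # k = 1, m = 0 reduces to the composition dot product
  expect_equal(mismatch_kernel("AC", "CA", 1, 0), 2)
  # frozen brute-force value for ("AA", "AC") at k = 2, m = 1: the 2-mers
  # AA and AC (Hamming distance 1) share 20 neighbours
  expect_equal(oracle_mismatch("AA", "AC", 2, 1), 20)
  expect_equal(mismatch_kernel("AA", "AC", 2, 1), 20)
  set.seed(42)
  for (rep in 1:15) {
    a <- random_protein(sample(3:8, 1))
    b <- random_protein(sample(3:8, 1))
    for (k in 2:3) {
      for (m in 0:1) {
        expect_equal(mismatch_kernel(a, b, k, m), oracle_mismatch(a, b, k, m))
      }
    }
  }
})

test_that("m = 0 mismatch kernel is the exact spectrum kernel", {
  spectrum <- function(a, b, k) {
    ka <- substring(a, 1:(nchar(a) - k + 1), k:nchar(a))
    kb <- substring(b, 1:(nchar(b) - k + 1), k:nchar(b))
    sum(outer(ka, kb, "=="))
  }
  set.seed(31)
  for (rep in 1:10) {
    a <- random_protein(10); b <- random_protein(12)
    expect_equal(mismatch_kernel(a, b, 3, 0), spectrum(a, b, 3))
  }
  expect_error(mismatch_kernel("AC", "ACD", 3, 1), "at least k")
  expect_error(mismatch_kernel("ACD", "ACD", 3, 3), "m < k")
})

test_that("SW kernel agrees with an established aligner on random pairs", {
  set.seed(2024)
  for (rep in 1:8) {
    a <- random_protein(sample(10:30, 1))
    b <- random_protein(sample(10:30, 1))
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 1,
      scoreOnly = TRUE
    )
    expect_equal(sw_kernel(a, b), max(ref, 0))
  }
})

test_that("gram() evaluates each unordered pair once and preserves ids", {
  items <- list(x = 2, y = 3, z = 5)
  g <- gram(items, function(a, b) a * b, kernel_name = "product")
  expect_s3_class(g, "gram_matrix")
  expect_equal(g$ids, c("x", "y", "z"))
  expect_equal(g$values["x", "z"], 10)
  expect_equal(g$values, t(g$values))
  # single item
  g1 <- gram(list(q = 4), function(a, b) a + b)
  expect_equal(unname(g1$values), matrix(8))
  # permuting items permutes rows/columns consistently
  g2 <- gram(items[c(3, 1, 2)], function(a, b) a * b)
  expect_equal(g2$values[g$ids, g$ids], g$values)
  expect_error(gram(items, function(a, b) stop("boom")), "x.*y|boom")
})

test_that("chain_gram matches elementwise kernels and supports normalization", {
  set.seed(8)
  chains <- random_chain_tbl(4, c(8, 15))
  for (kern in c("sw", "la", "mismatch")) {
    g <- chain_gram(chains, kern, k = 3, m = 1)
    fun <- switch(kern,
      sw = function(a, b) sw_kernel(a, b),
      la = function(a, b) la_kernel(a, b),
      mismatch = function(a, b) mismatch_kernel(a, b, 3, 1))
    for (idx in list(c(1, 2), c(2, 4), c(3, 3))) {
      expect_equal(g$values[idx[1], idx[2]],
                   fun(chains$sequence[idx[1]], chains$sequence[idx[2]]))
    }
  }
  gn <- chain_gram(chains, "mismatch", k = 3, m = 1, normalize = TRUE)
  expect_equal(unname(diag(gn$values)), rep(1, 4))
  expect_true(all(abs(gn$values) <= 1 + 1e-12))
})

test_that("PSD correction shifts the diagonal by the most negative eigenvalue", {
  g <- seqaffinity:::new_gram_matrix(c("a", "b"), matrix(c(0, 1, 1, 0), 2),
                                     "toy")
  # eigenvalues of [[0,1],[1,0]] are +/- 1; the shift adds 1 to the diagonal
  corrected <- psd_correct(g)
  expect_equal(unname(corrected$values), matrix(c(1, 1, 1, 1), 2))
  expect_true(corrected$psd_corrected)
  expect_equal(corrected$lambda_min_removed, -1)
  expect_equal(min(eigen(corrected$values, symmetric = TRUE)$values), 0,
               tolerance = 1e-12)

  # already-PSD input is unchanged
  psd <- seqaffinity:::new_gram_matrix(c("a", "b"), diag(2), "toy")
  out <- psd_correct(psd)
  expect_equal(out$values, psd$values)
  expect_equal(out$lambda_min_removed, 0)

  # idempotence
  expect_equal(psd_correct(corrected)$values, corrected$values)
})

test_that("PSD correction guarantees a non-negative spectrum on random matrices", {
  set.seed(123)
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    m <- matrix(rnorm(n * n), n)
    m <- (m + t(m)) / 2
    g <- seqaffinity:::new_gram_matrix(as.character(seq_len(n)), m, "random")
    out <- psd_correct(g)
    expect_gte(min(eigen(out$values, symmetric = TRUE)$values), -1e-8)
    expect_equal(psd_correct(out)$values, out$values)
  }
})

test_that("Gram matrices round-trip through the delimited text format", {
  set.seed(9)
  chains <- random_chain_tbl(3, c(10, 14))
  g <- psd_correct(chain_gram(chains, "sw"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gram(g, path)
  back <- read_gram(path)
  expect_equal(back$ids, g$ids)
  expect_equal(back$values, g$values)
  expect_equal(back$kernel_name, g$kernel_name)
  expect_true(back$psd_corrected)
  expect_equal(back$lambda_min_removed, g$lambda_min_removed)
})
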