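test_that("FASTA round trip preserves ids and sequences exactly", {
  chains <- tibble::tibble(
    id = c("chainA", "chainB", "chainC"),
    sequence = c("MKV", "ACDEFGHIKLMNPQRSTVWY", "GGG")
  )
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(chains, path)
  back <- read_fasta(path)
  expect_equal(back$id, chains$id)
  expect_equal(back$sequence, chains$sequence)
  # byte-stable writer
  path2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(chains, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("read_fasta parses records in order and rejects degenerate files", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">A desc text", "MKV", ">B", "ACD", "EFG"), path)
  chains <- read_fasta(path)
  expect_equal(chains$id, c("A", "B"))
  expect_equal(chains$sequence, c("MKV", "ACDEFG"))

  writeLines(character(), path)
  expect_error(read_fasta(path), "FASTA")
  writeLines(c(">A", "MKV", ">empty", ""), path)
  expect_error(read_fasta(path), "empty sequence")
})

test_that("sanitization maps ambiguity codes and replaces unknowns with warning", {
  expect_equal(sanitize_sequence("mkv"), "MKV")
  # B->D, Z->E, U->C, O->K resolve silently
  expect_equal(sanitize_sequence("BZUO"), "DECK")
  expect_warning(out <- sanitize_sequence("MXKJV"), "replaced by 'A'")
  expect_equal(out, "MAKAV")
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">A", "MKXV"), path)
  expect_warning(chains <- read_fasta(path), "replaced")
  expect_equal(chains$sequence, "MKAV")
})

test_that("complex table parsing resolves chains and validates references", {
  chains <- tibble::tibble(id = c("A", "B", "C"),
                           sequence = c("MKV", "ACD", "EFGH"))
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("complex_id,ligand_chains,receptor_chains,delta_g,kd",
               "C1,A;B,C,-10.0,", "C2,C,A,-8.5,"), path)
  ds <- read_complex_table(path, chains)
  expect_s3_class(ds, "complex_dataset")
  expect_equal(n_complexes(ds), 2)
  expect_equal(ds$complexes$ligand[[1]], c("A", "B"))
  expect_equal(ds$complexes$receptor[[1]], "C")
  expect_equal(ds$complexes$delta_g, c(-10.0, -8.5))

  writeLines(c("complex_id,ligand_chains,receptor_chains,delta_g,kd",
               "C1,A;Z,C,-10.0,"), path)
  expect_error(read_complex_table(path, chains), "Z")

  writeLines(c("complex_id,ligand_chains,receptor_chains,delta_g,kd",
               "C1,A,C,-10.0,", "C1,B,C,-9.0,"), path)
  expect_error(read_complex_table(path, chains), "Duplicate")
})

test_that("inconsistent delta_g / kd pairs trigger a validation warning", {
  chains <- tibble::tibble(id = c("A", "B"), sequence = c("MKV", "ACD"))
  ok_kd <- delta_g_to_kd(-10)
  make <- function(kd) tibble::tibble(
    complex_id = "C1", ligand = list("A"), receptor = list("B"),
    delta_g = -10, kd = kd)
  expect_silent(complex_dataset(chains, make(ok_kd)))
  expect_warning(complex_dataset(chains, make(ok_kd * 1.05)), "disagree")
})

test_that("PSI-BLAST ASCII PSSM parsing keeps 20 log-odds per residue", {
  path <- withr::local_tempfile(fileext = ".pssm")
  header <- c("", "Last position-specific scoring matrix computed",
              paste0("     ", paste(AA20, collapse = "  ")))
  rows <- c(
    paste("  1 M ", paste(1:20, collapse = " "), paste(rep(0, 22), collapse = " ")),
    paste("  2 K ", paste(rep(0, 20), collapse = " "), paste(rep(0, 22), collapse = " ")),
    paste("  3 V ", paste(20:1, collapse = " "), paste(rep(0, 22), collapse = " "))
  )
  footer <- c("", "                      K         Lambda", "Standard Ungapped 0.13 0.31")
  writeLines(c(header, rows, footer), path)
  prof <- read_pssm_ascii(path, chain_id = "A")
  expect_equal(nrow(prof), 3)
  expect_equal(prof$residue, c("M", "K", "V"))
  expect_equal(unname(unlist(prof[1, AA20])), as.numeric(1:20))
  expect_equal(unname(unlist(prof[3, AA20])), as.numeric(20:1))

  writeLines(c(header, "  1 M  1 2 3", footer), path)
  expect_error(read_pssm_ascii(path), "line")
})

test_that("delta G / Kd conversion follows exp(dG / RT) and inverts", {
  expect_equal(delta_g_to_kd(0), 1.0)
  # frozen from an independent evaluation of exp(-9.556 / (1.9872e-3 * 298.15))
  expect_equal(delta_g_to_kd(-9.556), 9.894375333499075e-08, tolerance = 1e-12)
  for (x in c(-18, -4)) {
    expect_equal(kd_to_delta_g(delta_g_to_kd(x)), x, tolerance = 1e-12)
  }
  # strictly increasing in delta G; dG < 0 <=> Kd < 1 at any temperature
  dg <- seq(-18, 2, by = 0.5)
  for (temp in c(277, 298.15, 310)) {
    kd <- delta_g_to_kd(dg, temperature = temp)
    expect_true(all(diff(kd) > 0))
    expect_equal(kd < 1, dg < 0)
  }
  expect_error(delta_g_to_kd(Inf), "finite")
  expect_error(delta_g_to_kd(-5, temperature = 0), "positive")
  expect_error(kd_to_delta_g(-1), "positive")
})

test_that("dataset validation guards cross-validation entry points", {
  ds <- tiny_dataset()
  one <- complex_dataset(ds$chains, ds$complexes[1, ])
  expect_error(loco_cv(one), "at least 3")
  expect_error(complex_dataset(ds$chains,
                               tibble::tibble(complex_id = "X",
                                              ligand = list(character()),
                                              receptor = list("A"),
                                              delta_g = -5, kd = NA_real_)),
               "at least one")
})

test_that("extract_complex resolves chain sequences per side", {
  ds <- tiny_dataset()
  cx <- extract_complex(ds, "C1")
  expect_equal(cx$ligand$id, c("A", "B"))
  expect_equal(cx$receptor$sequence, "MNPQRSTVWY")
  expect_equal(cx$delta_g, -10)
  expect_error(extract_complex(ds, "nope"), "No complex")
})
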