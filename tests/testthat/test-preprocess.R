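make_counts <- function(m) {
  dimnames(m) <- list(paste0("g", seq_len(nrow(m))), paste0("s", seq_len(ncol(m))))
  m
}

test_that("counts-table parser handles the featureCounts dialect and bad input", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "c.tsv")
  writeLines(c("# featureCounts v1.6.4",
               "Geneid\tChr\tStart\tEnd\tStrand\tLength\ts1\ts2\ts3",
               "gA\tchr1\t1\t100\t+\t100\t0\t5\t2",
               "gB\tchr2\t5\t305\t-\t300\t7\t0\t9"), path)
  cm <- read_counts_table(path)
  expect_equal(dim(cm), c(2L, 3L))
  expect_equal(unname(cm$counts["gA", ]), c(0, 5, 2))
  expect_equal(unname(cm$lengths), c(100, 300))

  writeLines(c("Geneid\tChr\tStart\tEnd\tStrand\tLength\ts1",
               "gA\tchr1\t1\t100\t+\t100\t3.7"), path)
  expect_error(read_counts_table(path), "line 2.*3\\.7")

  writeLines(c("Geneid\tChr\tStart\tEnd\tStrand\tLength\ts1",
               "gA\tchr1\t1\t100\t+\t100\t3",
               "gA\tchr1\t1\t100\t+\t100\t4"), path)
  expect_error(read_counts_table(path), "line 3.*gA")

  writeLines(c("Geneid\tChr\tStart\tEnd\tStrand\tLength\ts1",
               "gA\tchr1\t1\t100\t+\t100\t3\t4"), path)
  expect_error(read_counts_table(path), "line 2")
})

test_that("zero-mean-group filter follows its definition and the brute-force oracle", {
  m <- make_counts(rbind(c(0, 0, 5, 5, 9, 9),   # all-zero in group a -> removed
                         c(1, 0, 2, 0, 1, 0),   # >=1 nonzero everywhere -> kept
                         c(3, 3, 0, 0, 2, 2)))  # all-zero in group b -> removed
  sheet <- data.frame(sample_id = colnames(m),
                      group = rep(c("a", "b", "c"), each = 2))
  kept <- filter_zero_mean_genes(m, sheet)
  expect_equal(rownames(kept), "g2")

  set.seed(1)
  for (i in 1:20) {
    m <- make_counts(matrix(rbinom(20 * 9, 2, 0.25), 20))
    sheet <- data.frame(sample_id = colnames(m),
                        group = rep(c("x", "y", "z"), each = 3))
    got <- suppressWarnings(filter_zero_mean_genes(m, sheet))
    expect_identical(got, filter_brute(m, sheet$group))
  }

  all0 <- make_counts(matrix(0, 3, 4))
  sheet0 <- data.frame(sample_id = colnames(all0), group = rep(c("a", "b"), 2))
  expect_warning(out <- filter_zero_mean_genes(all0, sheet0), "empty matrix")
  expect_equal(nrow(out), 0L)
})

test_that("median-of-ratios size factors match hand computation and are equivariant", {
  m <- make_counts(matrix(c(2, 8, 4, 16), 2))
  expect_equal(unname(estimate_size_factors(m)),
               c(2 / sqrt(8), 4 / sqrt(8)), tolerance = 1e-12)
  expect_equal(round(unname(estimate_size_factors(m)), 3), c(0.707, 1.414))

  # identical columns -> all factors equal (and equal to 1: ratio is constant 1)
  mi <- make_counts(matrix(rep(c(3, 9, 27), 4), 3))
  expect_equal(unname(estimate_size_factors(mi)), rep(1, 4))

  # scaling one column by 10 scales its factor by 10 relative to the others
  # (the pure median-of-ratios scale shifts all factors by the common
  # geometric-mean change of the reference, so ratios are the invariant)
  set.seed(2)
  m <- make_counts(matrix(rnbinom(200, mu = 50, size = 5) + 1, 50))
  sf <- estimate_size_factors(m)
  m2 <- m; m2[, 2] <- m2[, 2] * 10
  sf2 <- estimate_size_factors(m2)
  expect_equal((sf2[2] / sf2[1]) / (sf[2] / sf[1]), 10,
               tolerance = 1e-12, ignore_attr = TRUE)
  ratio <- sf2[-2] / sf[-2]  # unscaled samples shift by a common constant
  expect_equal(max(ratio) - min(ratio), 0, tolerance = 1e-12)

  # invariant to gene reordering
  perm <- sample(nrow(m))
  expect_equal(estimate_size_factors(m[perm, ]), sf, tolerance = 1e-12)

  # pseudo-reference fallback when no gene is positive everywhere
  msp <- make_counts(rbind(c(4, 0, 8), c(0, 6, 12), c(10, 5, 0)))
  expect_warning(sfp <- estimate_size_factors(msp), "pseudo-reference")
  expect_true(all(sfp > 0))
})

test_that("normalization arithmetic and the log transform behave as specified", {
  m <- make_counts(matrix(c(9, 0, 4, 2), 2))
  nm <- normalize_counts(m, size_factors = c(0.5, 2))
  expect_equal(unname(nm$norm[1, ]), c(18, 2))
  expect_equal(nm$log2["g1", "s1"], log2(19))
  expect_equal(nm$log2["g2", "s1"], 0)  # zero count, pseudocount 1
  ident <- normalize_counts(m, size_factors = c(1, 1))
  expect_equal(ident$norm, m)
  expect_error(normalize_counts(m, size_factors = 1), "one size factor")
})

test_that("TPM columns are rate-normalized to one million", {
  m <- make_counts(matrix(c(10, 30), 2))
  tpm <- compute_tpm(m, lengths = c(100, 300))
  expect_equal(unname(tpm[, 1]), c(5e5, 5e5))

  single <- make_counts(matrix(7, 1))
  expect_equal(unname(compute_tpm(single, lengths = 50)[1, 1]), 1e6)

  sim <- tiny_sim()
  tpm <- compute_tpm(sim$counts)
  expect_equal(unname(colSums(tpm)), rep(1e6, 24), tolerance = 1e-9)

  mz <- make_counts(matrix(c(5, 3, 0, 0), 2))
  expect_warning(tz <- compute_tpm(mz, lengths = c(10, 10)), "all-zero")
  expect_equal(unname(tz[, 2]), c(0, 0))
})

test_that("batch removal recovers a planted balanced shift and is idempotent", {
  set.seed(4)
  sheet <- data.frame(sample_id = paste0("s", 1:12),
                      group = rep(c("SCC", "Pap", "Ctrl"), each = 4),
                      batch = rep(c("b1", "b2"), 6))  # balanced across groups
  # base matrix with exact group structure: no incidental batch component
  effects <- matrix(rnorm(50 * 3, mean = 6), 50)
  base <- effects[, as.integer(factor(sheet$group, unique(sheet$group)))]
  dimnames(base) <- list(paste0("g", 1:50), sheet$sample_id)
  delta <- 1.7
  shifted <- base
  shifted[, sheet$batch == "b2"] <- shifted[, sheet$batch == "b2"] + delta
  corrected <- remove_batch_effect(shifted, sheet)
  expect_equal(corrected, base, tolerance = 1e-8)
  # idempotence
  expect_equal(remove_batch_effect(corrected, sheet), corrected, tolerance = 1e-8)
  # linearity on noisy data: a planted shift changes nothing after correction
  noisy <- base + matrix(rnorm(length(base)), nrow(base))
  noisy_shifted <- noisy
  noisy_shifted[, sheet$batch == "b2"] <- noisy_shifted[, sheet$batch == "b2"] + delta
  expect_equal(remove_batch_effect(noisy_shifted, sheet),
               remove_batch_effect(noisy, sheet), tolerance = 1e-8)
  # single batch: identity
  sheet1 <- sheet; sheet1$batch <- "b1"
  expect_identical(remove_batch_effect(shifted, sheet1), shifted)
  # batch confounded with group: rank-deficient design is refused
  sheetc <- sheet; sheetc$batch <- sheetc$group
  expect_error(remove_batch_effect(shifted, sheetc), "confounded")
})

test_that("batch removal agrees with the reference limma implementation", {
  skip_if_not_installed("limma")
  set.seed(9)
  y <- matrix(rnorm(40 * 10, 5), 40,
              dimnames = list(paste0("g", 1:40), paste0("s", 1:10)))
  sheet <- data.frame(sample_id = colnames(y),
                      group = rep(c("SCC", "Pap"), each = 5),
                      batch = rep(c("b1", "b2"), 5))
  ours <- remove_batch_effect(y, sheet)
  ref <- limma::removeBatchEffect(y, batch = factor(sheet$batch),
                                  design = stats::model.matrix(~factor(sheet$group)))
  # limma centers the batch term (sum-to-zero coding); reference coding shifts
  # each gene by a constant instead, so the two agree up to a per-gene offset
  offset <- ours - ref
  expect_lt(max(apply(offset, 1, function(v) diff(range(v)))), 1e-10)
  # and the batch-corrected between-sample differences coincide exactly
  expect_equal(apply(ours, 1, diff), apply(ref, 1, diff), tolerance = 1e-10)
})

test_that("PCA is a faithful centered SVD of the samples", {
  # exact line through the centroid: one component carries all variance
  line <- outer(c(1, 2, 3), c(-1, 0, 1, 2))
  dimnames(line) <- list(paste0("g", 1:3), paste0("s", 1:4))
  p <- pca_samples(line, 1)
  expect_equal(p$var_explained[1], 1)

  set.seed(6)
  y <- matrix(rnorm(30 * 8), 30,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:8)))
  p <- pca_samples(y, 7)
  expect_true(all(diff(p$var_explained) <= 1e-12))
  expect_lte(sum(p$var_explained), 1 + 1e-12)
  # all components kept: scores reproduce pairwise distances of centered data
  centered <- y - rowMeans(y)
  expect_equal(unname(as.matrix(dist(p$scores))),
               unname(as.matrix(dist(t(centered)))), tolerance = 1e-8)
  expect_error(pca_samples(y, 8), "n_components")
})
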