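test_that("genomic inflation is calibrated and monotone", {
  n <- 1e5
  p <- (seq_len(n) - 0.5) / n
  expect_equal(genomic_inflation(p), 1, tolerance = 1e-3)
  expect_gt(genomic_inflation(p / 2), 1)
  expect_error(genomic_inflation(numeric(0)), "empty")
  expect_error(genomic_inflation(c(0.5, 0)), "0, 1")
})

test_that("run_scan on a null panel: no hits, calibrated inflation, no drops", {
  sig <- sigma2_matrix()
  fx <- make_trait_fixtures(500, sig, seed = 55)
  res <- run_scan(fx$files, config = list(column_map = cmap_beta, sigma = sig))
  expect_s3_class(res, "scan_result")
  expect_equal(nrow(res), 500L)             # row count equals panel size
  expect_equal(sum(res$significant), 0L)
  l <- attr(res, "lambda_gc")
  expect_true(all(l > 0.8 & l < 1.25))
  # per-trait p columns match the input z-scores
  expect_equal(res[[4]], 2 * pnorm(abs(fx$z[, 1]), lower.tail = FALSE),
               tolerance = 1e-10)
  # re-running with identical inputs is identical
  res2 <- run_scan(fx$files, config = list(column_map = cmap_beta, sigma = sig))
  expect_identical(res, res2)
})

test_that("run_scan can estimate sigma and accepts a sigma file", {
  sig <- exchangeable_correlation(3, 0.25)
  fx <- make_trait_fixtures(3000, sig, seed = 77)
  res <- run_scan(fx$files, config = list(column_map = cmap_beta,
                                          method = "interpolate"))
  est <- attr(res, "sigma")
  expect_lt(max(abs(est[lower.tri(est)] - 0.25)), 0.06)
  f <- tempfile(fileext = ".txt")
  write_correlation(trait_correlation(unclass(sig)), f)
  res2 <- run_scan(fx$files, config = list(column_map = cmap_beta, sigma = f,
                                           method = "interpolate"))
  expect_equal(nrow(res2), 3000L)
  expect_equal(unclass(attr(res2, "sigma")), unclass(unname(sig)),
               tolerance = 1e-9)
})

test_that("a single shared SNP yields a one-row result", {
  sig <- diag(2)
  d1 <- data.frame(SNP = c("rs1", "rs2"), CHR = "1", POS = c(1L, 2L),
                   A1 = "A", A2 = "C", BETA = c(1, 2), SE = 1)
  d2 <- data.frame(SNP = c("rs2", "rs3"), CHR = "1", POS = c(2L, 3L),
                   A1 = "A", A2 = "C", BETA = c(0.5, 1), SE = 1)
  f1 <- write_trait_file(d1, tempfile(fileext = ".tsv"))
  f2 <- write_trait_file(d2, tempfile(fileext = ".tsv"))
  res <- run_scan(c(f1, f2), config = list(column_map = cmap_beta, sigma = sig))
  expect_equal(nrow(res), 1L)
  expect_equal(res$snp, "rs2")
})

test_that("select_hits filters, restricts and sorts by OMNI p-value", {
  sig <- sigma2_matrix()
  fx <- make_trait_fixtures(200, sig, seed = 60)
  res <- run_scan(fx$files, config = list(column_map = cmap_beta, sigma = sig))
  all_rows <- select_hits(res, threshold = 1)
  expect_equal(nrow(all_rows), 200L)
  expect_true(!is.unsorted(all_rows$p_omni))
  none <- select_hits(res)  # default genome-wide threshold, null panel
  expect_equal(nrow(none), 0L)
  some <- select_hits(res, independent_snps = all_rows$snp[1:3], threshold = 1)
  expect_equal(nrow(some), 3L)
})
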