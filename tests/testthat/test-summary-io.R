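test_that("read_trait_summary computes z from each encoding and skips bad rows", {
  df <- data.frame(SNP = c("rs1", "rs2", "rs3"), CHR = "1",
                   POS = c(100L, 200L, 300L), A1 = c("A", "C", "G"),
                   A2 = c("C", "T", "A"),
                   BETA = c(0.12, -0.4, 0.05), SE = c(0.04, 0.1, 0.02))
  f <- write_trait_file(df, tempfile(fileext = ".tsv"))
  ts <- read_trait_summary(f, cmap_beta, trait_name = "t1")
  expect_equal(ts$z, df$BETA / df$SE, tolerance = 1e-12)
  expect_equal(attr(ts, "n_skipped"), 0L)

  # p + direction: z = direction * qnorm(1 - p/2)
  dfp <- data.frame(SNP = "rs1", CHR = "12", POS = 1L, A1 = "A", A2 = "G",
                    P = 1.94e-3, DIR = 1)
  fp <- write_trait_file(dfp, tempfile(fileext = ".tsv"))
  tp <- read_trait_summary(fp, cmap_p)
  expect_equal(tp$z, qnorm(1.94e-3 / 2, lower.tail = FALSE), tolerance = 1e-12)

  # se = 0 rows are skipped, not fatal
  df$SE[2] <- 0
  f2 <- write_trait_file(df, tempfile(fileext = ".tsv"))
  t2 <- read_trait_summary(f2, cmap_beta)
  expect_equal(attr(t2, "n_skipped"), 1L)
  expect_equal(nrow(t2), 2L)

  expect_error(read_trait_summary(f, list(snp = "SNP")), "column_map")
  badmap <- cmap_beta; badmap$beta <- "NOPE"
  expect_error(read_trait_summary(f, badmap), "not found")

  # gzip-compressed input is accepted
  dfz <- data.frame(SNP = c("rs1", "rs2"), CHR = "1", POS = c(10L, 20L),
                    A1 = "A", A2 = "C", BETA = c(0.12, -0.4), SE = c(0.04, 0.1))
  fgz <- tempfile(fileext = ".tsv.gz")
  con <- gzfile(fgz, "w")
  write.table(dfz, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  tgz <- read_trait_summary(fgz, cmap_beta)
  expect_equal(tgz$z, dfz$BETA / dfz$SE, tolerance = 1e-12)
})

test_that("harmonize aligns alleles, flips swapped coding, drops palindromes", {
  mk <- function(snp, a1, a2, z) {
    df <- data.frame(SNP = snp, CHR = "1", POS = seq_along(snp) * 10L,
                     A1 = a1, A2 = a2, BETA = z, SE = 1)
    read_trait_summary(write_trait_file(df, tempfile(fileext = ".tsv")),
                       cmap_beta)
  }
  t1 <- mk(c("rs1", "rs2", "rs3"), c("A", "C", "A"), c("C", "T", "T"),
           c(1.0, -0.5, 2.0))
  # identical coding: z matrix equals stacked inputs (palindromic rs3 dropped)
  t2 <- mk(c("rs1", "rs2", "rs3"), c("A", "C", "A"), c("C", "T", "T"),
           c(0.3, 0.8, -1))
  pan <- harmonize(list(t1, t2))
  expect_equal(pan$snps$snp, c("rs1", "rs2"))
  expect_equal(unname(pan$z), cbind(c(1.0, -0.5), c(0.3, 0.8)))
  expect_true("drop_palindromic" %in% pan$flip_log$action)

  # swapped alleles at one SNP: z negated and logged
  t3 <- mk(c("rs1", "rs2"), c("C", "C"), c("A", "T"), c(0.3, 0.8))
  pan2 <- harmonize(list(t1, t3))
  expect_equal(unname(pan2$z[, 2]), c(-0.3, 0.8))
  expect_true(any(pan2$flip_log$action == "flip_sign" &
                  pan2$flip_log$snp == "rs1"))

  # palindromic SNPs can be kept on request
  pan3 <- harmonize(list(t1, t2), drop_palindromic = FALSE)
  expect_equal(nrow(pan3$z), 3L)

  # empty intersection errors
  t4 <- mk("rs9", "A", "C", 1)
  expect_error(harmonize(list(t1, t4)), "shared")

  # idempotence: re-harmonizing summaries rebuilt from the panel is a no-op
  rebuilt <- lapply(1:2, function(j) {
    df <- data.frame(SNP = pan$snps$snp, CHR = pan$snps$chrom,
                     POS = pan$snps$pos, A1 = pan$snps$ea, A2 = pan$snps$oa,
                     BETA = pan$z[, j], SE = 1)
    read_trait_summary(write_trait_file(df, tempfile(fileext = ".tsv")),
                       cmap_beta)
  })
  pan4 <- harmonize(rebuilt)
  expect_equal(unname(pan4$z), unname(pan$z))
  expect_equal(pan4$snps$snp, pan$snps$snp)
})

test_that("estimate_trait_correlation recovers the generating correlation", {
  sig <- exchangeable_correlation(3, 0.3)
  Z <- oracle_mvn(1e5, sig, 3)
  panel <- list(snps = data.frame(snp = sprintf("s%d", 1:1e5)),
                z = Z, trait_names = c("a", "b", "c"))
  est <- estimate_trait_correlation(panel)
  expect_lt(max(abs(est[lower.tri(est)] - 0.3)), 0.01)
  expect_equal(diag(est), c(a = 1, b = 1, c = 1))

  # iid columns: off-diagonals bounded by sampling error 3/sqrt(M)
  Z0 <- oracle_mvn(1e5, diag(3), 4)
  panel0 <- list(snps = panel$snps, z = Z0, trait_names = c("a", "b", "c"))
  est0 <- estimate_trait_correlation(panel0)
  expect_lt(max(abs(est0[lower.tri(est0)])), 3 / sqrt(1e5))

  # duplicated column gives exact correlation 1
  paneld <- list(snps = panel$snps[1:5000, , drop = FALSE],
                 z = cbind(Z[1:5000, ], Z[1:5000, 1]),
                 trait_names = c("a", "b", "c", "a2"))
  estd <- estimate_trait_correlation(paneld)
  expect_equal(estd["a", "a2"], 1, tolerance = 1e-12)

  # invariant to SNP row order
  ord <- sample(nrow(Z))
  panelp <- list(snps = panel$snps[ord, , drop = FALSE], z = Z[ord, ],
                 trait_names = panel$trait_names)
  expect_equal(unclass(estimate_trait_correlation(panelp)), unclass(est))

  # whitelist and null_z_cap restrict the SNP set
  wl <- sprintf("s%d", 1:5000)
  estw <- estimate_trait_correlation(panel, snp_whitelist = wl)
  expect_false(isTRUE(all.equal(estw[1, 2], est[1, 2], tolerance = 1e-12)))
  expect_error(estimate_trait_correlation(
    list(snps = panel$snps[1, , drop = FALSE], z = Z[1, , drop = FALSE],
         trait_names = panel$trait_names)),
    "fewer than 2")
})

test_that("correlation matrices round-trip through the text format", {
  sig <- trait_correlation(sigma2_matrix())
  dimnames(sig) <- list(c("HDL", "LDL", "TG"), c("HDL", "LDL", "TG"))
  f <- tempfile(fileext = ".txt")
  write_correlation(sig, f)
  back <- read_correlation(f)
  expect_equal(unclass(back), unclass(sig), tolerance = 1e-9)
  # headerless square matrix also parses
  f2 <- tempfile(fileext = ".txt")
  write.table(unclass(sig), f2, row.names = FALSE, col.names = FALSE)
  expect_equal(unclass(read_correlation(f2)), unclass(unname(sig)),
               tolerance = 1e-9)
})
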