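# shared fixtures and independent oracles used across test files

sigma1_matrix <- function() {
  # exchangeable 0.3 with the (1,3)/(3,1) pair at 0.5
  m <- matrix(0.3, 3, 3)
  m[1, 3] <- m[3, 1] <- 0.5
  diag(m) <- 1
  m
}

sigma2_matrix <- function() {
  matrix(c(1, -0.08, -0.42,
           -0.08, 1, 0.27,
           -0.42, 0.27, 1), 3, 3)
}

# independent Berk-Jones oracle at sigma = I: per-rank binomial likelihood
# ratio with its own bisection for the common mean shift
bj_oracle <- function(z) {
  K <- length(z)
  d <- sort(abs(z), decreasing = TRUE)
  best <- 0
  for (k in seq_len(K)) {
    t <- d[k]
    p0 <- 2 * pnorm(t, lower.tail = FALSE)
    if (!(p0 < k / K)) next
    f <- function(m) pnorm(t - m, lower.tail = FALSE) +
      pnorm(t + m, lower.tail = FALSE) - k / K
    if (f(0) >= 0 || f(t + 10) <= 0) next
    lo <- 0; hi <- t + 10
    for (i in 1:80) {
      mid <- (lo + hi) / 2
      if (f(mid) < 0) lo <- mid else hi <- mid
    }
    mu <- (lo + hi) / 2
    p1 <- pnorm(t - mu, lower.tail = FALSE) + pnorm(t + mu, lower.tail = FALSE)
    lr <- dbinom(k, K, p1, log = TRUE) - dbinom(k, K, p0, log = TRUE)
    best <- max(best, lr)
  }
  best
}

# draws an n x K null MVN panel with a fixed seed (independent of draw_z)
oracle_mvn <- function(n, sigma, seed) {
  set.seed(seed)
  K <- nrow(sigma)
  matrix(rnorm(n * K), n, K) %*% chol(sigma)
}

# write a small trait summary file; enc is one of "beta", "p", "z"
write_trait_file <- function(df, path, enc = "beta") {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# default column maps for fixture files
cmap_beta <- list(snp = "SNP", chrom = "CHR", pos = "POS",
                  effect_allele = "A1", other_allele = "A2",
                  beta = "BETA", se = "SE")
cmap_p <- list(snp = "SNP", chrom = "CHR", pos = "POS",
               effect_allele = "A1", other_allele = "A2",
               p = "P", direction = "DIR")

# simulate a K-trait fixture panel and write one summary file per trait;
# returns list(files, z) with the true Z matrix
make_trait_fixtures <- function(n_snp, sigma, seed, dir = tempfile("panel")) {
  dir.create(dir)
  K <- nrow(sigma)
  Z <- oracle_mvn(n_snp, sigma, seed)
  # allele pairs A/C and G/T are strand-unambiguous (non-palindromic)
  set.seed(seed + 1)
  ea <- sample(c("A", "G"), n_snp, replace = TRUE)
  oa <- ifelse(ea == "A", "C", "T")
  files <- character(K)
  for (j in seq_len(K)) {
    df <- data.frame(SNP = sprintf("rs%05d", seq_len(n_snp)),
                     CHR = rep("1", n_snp), POS = seq_len(n_snp) * 1000L,
                     A1 = ea, A2 = oa,
                     BETA = Z[, j], SE = rep(1, n_snp))
    files[j] <- write_trait_file(df, file.path(dir, paste0("trait", j, ".tsv")))
  }
  list(files = files, z = Z, dir = dir)
}
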