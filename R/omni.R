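#' Omnibus multi-trait association test for one SNP
#'
#' Runs the GBJ, GHC and MinP tests on the Z-score vector of one SNP and
#' combines their three p-values with equal weights 1/3 by the Cauchy
#' combination ([acat_combine()]), whose null validity does not depend on the
#' dependence among the component tests. The OMNI p-value is the headline
#' result: GBJ is the most powerful component under moderately sparse
#' signals, GHC and MinP under extreme sparsity, and the combination is
#' robust across signal patterns.
#'
#' @param z numeric vector of per-trait Z-scores for one SNP.
#' @param sigma K x K between-trait correlation matrix.
#' @param snp_id optional SNP label.
#' @param t0 GHC truncation threshold (default 0).
#' @return one-row `data.frame` with columns `snp_id`, `stat_gbj`,
#'   `stat_ghc`, `stat_minp`, `p_gbj`, `p_ghc`, `p_minp`, `omni_stat`,
#'   `p_omni`.
#' @export
#' @examples
#' sigma <- exchangeable_correlation(3, 0.3)
#' omni_test(c(1.2, -0.5, 2.8), sigma)
omni_test <- function(z, sigma, snp_id = NA_character_, t0 = 0) {
  check_z(z)
  K <- length(z)
  sigma <- as.matrix(sigma)
  if (K == 1L) {
    p1 <- 2 * norm_sf(abs(z))
    cc <- acat_combine(rep(p1, 3))
    return(data.frame(snp_id = snp_id, stat_gbj = 0, stat_ghc = abs(z),
                      stat_minp = abs(z), p_gbj = p1, p_ghc = p1, p_minp = p1,
                      omni_stat = cc$stat, p_omni = cc$pvalue,
                      stringsAsFactors = FALSE))
  }
  sg <- gbj_statistic(z, sigma)
  sh <- ghc_statistic(z, sigma, t0)
  sm <- max(abs(z))
  pg <- crossing_pvalue(sg, "GBJ", K, sigma)
  ph <- crossing_pvalue(sh, "GHC", K, sigma, t0 = t0)
  pm <- minp_pvalue(z, sigma)
  cc <- acat_combine(c(pg, ph, pm))
  data.frame(snp_id = snp_id, stat_gbj = sg, stat_ghc = sh, stat_minp = sm,
             p_gbj = pg, p_ghc = ph, p_minp = pm,
             omni_stat = cc$stat, p_omni = cc$pvalue, stringsAsFactors = FALSE)
}

#' P-values of all four tests for a matrix of Z-vectors
#'
#' Computes GBJ, GHC, MinP and OMNI p-values for each row of `Z`. The
#' analytic p-value of each supremum statistic is a fixed monotone function
#' of the statistic given `sigma`, so for large `n` the default evaluates the
#' exact crossing p-value on a grid of observed statistic values and maps the
#' rest by monotone interpolation of log p (`method = "interpolate"`, grid
#' size `n_grid`); `method = "exact"` inverts every row individually.
#'
#' @param Z n x K matrix of Z-scores (rows = SNPs or replicates).
#' @param sigma between-trait correlation matrix.
#' @param method `"exact"` or `"interpolate"`.
#' @param n_grid grid size for the interpolated path.
#' @param t0 GHC truncation threshold.
#' @return n x 4 matrix with columns `p_gbj`, `p_ghc`, `p_minp`, `p_omni`.
#' @export
multi_trait_pvalues <- function(Z, sigma, method = c("interpolate", "exact"),
                                n_grid = 256L, t0 = 0) {
  method <- match.arg(method)
  Z <- as.matrix(Z)
  K <- ncol(Z)
  sigma <- as.matrix(sigma)
  if (K == 1L) {
    p1 <- 2 * norm_sf(abs(Z[, 1]))
    return(cbind(p_gbj = p1, p_ghc = p1, p_minp = p1, p_omni = p1))
  }
  if (method == "exact") {
    res <- t(apply(Z, 1L, function(z) {
      r <- omni_test(z, sigma, t0 = t0)
      c(r$p_gbj, r$p_ghc, r$p_minp, r$p_omni)
    }))
    colnames(res) <- c("p_gbj", "p_ghc", "p_minp", "p_omni")
    return(res)
  }
  n_grid <- min(n_grid, max(48L, nrow(Z) %/% 8L))
  sg <- gbj_stat_matrix(Z, sigma)
  sh <- ghc_stat_matrix(Z, sigma, t0)
  sm <- apply(abs(Z), 1L, max)
  # the GBJ p-value jumps from 1 at statistic 0 to its continuous branch just
  # above; interpolate only over the positive statistics
  pg <- rep(1, nrow(Z))
  pos <- sg > 0
  if (any(pos))
    pg[pos] <- interp_pvalues(sg[pos],
                              function(s) crossing_pvalue(s, "GBJ", K, sigma),
                              n_grid)
  ph <- interp_pvalues(sh, function(s) crossing_pvalue(s, "GHC", K, sigma, t0 = t0), n_grid)
  pm <- interp_pvalues(sm, function(s) minp_from_threshold(s, sigma), n_grid)
  po <- acat_rows(cbind(pg, ph, pm))
  cbind(p_gbj = pg, p_ghc = ph, p_minp = pm, p_omni = po)
}

# evaluate pfun exactly on a quantile grid of the statistic values and map
# all values by monotone (linear in log p) interpolation
interp_pvalues <- function(stat, pfun, n_grid = 256L) {
  ux <- sort(unique(stat))
  if (length(ux) <= n_grid) {
    grid <- ux
  } else {
    # quantile spacing resolves the bulk; uniform and log spacing resolve the
    # upper tail, where log p is strongly convex in heavy-tailed statistics
    half <- max(n_grid %/% 2L, 16L)
    grid <- c(
      quantile(ux, probs = seq(0, 1, length.out = half), type = 7, names = FALSE),
      seq(min(ux), max(ux), length.out = half))
    if (max(ux) > 0) {
      lo <- max(min(ux[ux > 0]), max(ux) * 1e-3)
      grid <- c(grid, exp(seq(log(lo), log(max(ux)), length.out = half)))
    }
    grid <- sort(unique(grid))
  }
  pg <- vapply(grid, pfun, 0)
  pg <- pmax(rev(cummax(rev(pg))), 1e-300)  # enforce monotone non-increasing
  if (length(grid) == 1L) return(rep(pg, length(stat)))
  exp(approx(grid, log(pg), xout = stat, rule = 2)$y)
}
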