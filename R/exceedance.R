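#' Count two-sided exceedances
#'
#' `S(t) = sum_k 1{|z_k| >= t}`, the number of traits whose absolute Z-score
#' reaches threshold `t`. The inequality is closed: a Z-score exactly at the
#' threshold counts.
#'
#' @param z numeric vector of Z-scores.
#' @param t non-negative threshold.
#' @return integer in `0..K`.
#' @export
#' @examples
#' exceedance_count(c(2, -3, 0.5), 1.5)  # 2
exceedance_count <- function(z, t) {
  check_z(z)
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stop("`t` must be a single non-negative number")
  sum(abs(z) >= t)
}

# Mehler/Hermite series for the covariance of the two-sided exceedance
# indicators of a bivariate standard normal pair with correlation rho and a
# common mean shift mu:
#   Cov( 1{|Z_i| >= t}, 1{|Z_j| >= t} ),  Z ~ N(mu, 1) pairwise corr rho.
# With a = t - mu, b = t + mu and h_m = He_m/sqrt(m!) the series is
#   sum_{n>=1} rho^n / n * ( phi(a) h_{n-1}(a) + (-1)^n phi(b) h_{n-1}(b) )^2
# (a perfect square per term, so all terms are >= 0 when rho > 0, giving good
# relative accuracy deep in the tail). Vectorized over t (and mu).
exceed_cov_series <- function(t, rho, mu = 0, tol = 1e-16, nmax = 1500L) {
  a <- t - mu
  b <- t + mu
  pa <- dnorm(a); pb <- dnorm(b)
  hpa <- rep(0, length(a)); hca <- rep(1, length(a))
  hpb <- rep(0, length(b)); hcb <- rep(1, length(b))
  acc <- numeric(length(a))
  rn <- 1
  # only even-order terms are accumulated: at mu = 0 the odd terms vanish
  # identically, and for mu != 0 this takes the even part in rho, i.e. the
  # covariance averaged over the two sign conventions of the pair — allele
  # coding is arbitrary, so the tests must not depend on trait signs
  for (n in seq_len(nmax)) {
    u <- pa * hca
    v <- pb * hcb
    rn <- rn * rho
    if (n %% 2L == 0L) {
      sq <- u + v
      acc <- acc + rn / n * sq * sq
    }
    if (n > 20L && abs(rn) / n * max((abs(u) + abs(v))^2) < tol) break
    na_ <- (a * hca - sqrt(n - 1) * hpa) / sqrt(n)
    nb_ <- (b * hcb - sqrt(n - 1) * hpb) / sqrt(n)
    hpa <- hca; hca <- na_
    hpb <- hcb; hcb <- nb_
  }
  acc
}

# covariance at |rho| = 1 or numerically close to it (degenerate pairs):
# the two indicators are identical because |Z_j| = |Z_i| when Z_j = +/- Z_i
# and mu = 0; with a mean shift and rho = -1 the overlap is computed directly.
exceed_cov_degenerate <- function(t, rho, mu = 0) {
  a <- t - mu
  b <- t + mu
  p1 <- norm_sf(a) + norm_sf(b)
  # rho = +1: the indicators coincide. rho = -1: Z_j = -Z_i, so indicator_j
  # = 1{eps <= -a or eps >= b} with eps = Z_i - mu. The even part (average
  # over the two signs) is returned, mirroring the series route.
  pos <- p1 - p1^2
  if (mu == 0) return(pos)
  m <- pmax(a, b)
  p11 <- norm_sf(m) + pnorm(-m) + ifelse(a < 0, pnorm(-a) - pnorm(a), 0)
  (pos + (p11 - p1^2)) / 2
}

#' Pairwise covariance of exceedance indicators
#'
#' `Cov(1{|Z_i| >= t}, 1{|Z_j| >= t})` for a bivariate standard normal pair
#' with correlation `rho`, optionally under a common mean shift `mu`. Computed
#' by the Mehler (Hermite-polynomial) expansion of the bivariate normal
#' density; for `|rho|` at or extremely near 1 the degenerate closed form is
#' used. An even function of `rho` when `mu = 0`.
#'
#' @param t non-negative threshold (vectorized).
#' @param rho correlation in `[-1, 1]`.
#' @param mu common mean shift (default 0).
#' @return covariance value(s).
#' @export
#' @examples
#' pair_exceedance_cov(1, 0)    # independence: 0
#' pair_exceedance_cov(2, 0.5)
pair_exceedance_cov <- function(t, rho, mu = 0) {
  if (!is.numeric(rho) || length(rho) != 1L || is.na(rho) || abs(rho) > 1)
    stop("`rho` must be a single value in [-1, 1]")
  if (any(t < 0)) stop("`t` must be non-negative")
  if (rho == 0) return(rep(0, length(t)))
  if (abs(rho) > 0.9995) return(exceed_cov_degenerate(t, rho, mu))
  exceed_cov_series(t, rho, mu)
}

#' Variance of the exceedance count
#'
#' `Var(S(t))` for `S(t) = sum_k 1{|Z_k| >= t}` with `Z ~ MVN(mu * 1, sigma)`:
#' the sum of the K Bernoulli variances plus all pairwise covariances from
#' [pair_exceedance_cov()]. Depends on `sigma` only through even functions of
#' its entries when `mu = 0`, so it is invariant under sign flips of traits.
#'
#' @param t threshold (vectorized).
#' @param sigma between-trait correlation matrix.
#' @param mu common per-trait mean shift (default 0, the null).
#' @return variance value(s), same length as `t`.
#' @export
var_exceedance_count <- function(t, sigma, mu = 0) {
  sigma <- as.matrix(sigma)
  K <- nrow(sigma)
  if (any(t < 0)) stop("`t` must be non-negative")
  p1 <- norm_sf(t - mu) + norm_sf(t + mu)
  v <- K * p1 * (1 - p1)
  if (K > 1) {
    rhos <- sigma[lower.tri(sigma)]
    for (r in unique(rhos)) {
      if (r == 0) next
      mult <- 2 * sum(rhos == r)
      v <- v + mult * pair_exceedance_cov(t, r, mu)
    }
  }
  pmax(v, 0)
}
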