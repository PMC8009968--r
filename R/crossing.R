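# Boundary-crossing probability engine.
#
# Every supremum-based test here rejects when the ordered |Z| statistics cross
# a non-increasing boundary: p = P(exists k: |Z|_(K-k+1) >= t_k). Writing
# S(t) for the exceedance count, the no-crossing event is
# {S(t_k) <= k-1 for all k}. The counts S(t_1) <= ... <= S(t_K) are treated
# as a Markov chain: conditional on S(t_{k-1}) = s, the K - s scores still
# below t_{k-1} each fall below t_k independently in the binomial case, and
# under correlation the increment is modeled as extended beta-binomial with
# the exact conditional success probability
#   p_k = (q_k - q_{k-1}) / (1 - q_{k-1}),  q_k = 2 Phibar(t_k),
# and a dispersion chosen so the implied marginal variance of S(t_k) matches
# Var(S(t_k)) from the correlation matrix. The recursion is exact when
# sigma = I (it reduces to the classical iid order-statistic recursion) and
# the crossing mass is accumulated level by level from the EBB upper tails,
# which keeps full relative accuracy for very small p-values.

# Gauss-Hermite nodes/weights for the standard normal weight (probabilists'
# polynomials via Golub-Welsch); weights sum to 1
.gh_cache <- new.env(parent = emptyenv())
gauss_hermite_norm <- function(n) {
  key <- as.character(n)
  if (!is.null(.gh_cache[[key]])) return(.gh_cache[[key]])
  i <- seq_len(n - 1)
  b <- sqrt(i)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  res <- list(x = e$values, w = e$vectors[1, ]^2)
  .gh_cache[[key]] <- res
  res
}

# is sigma exchangeable with a common non-negative off-diagonal rho?
exchangeable_rho <- function(sigma) {
  K <- nrow(sigma)
  if (K < 2) return(0)
  off <- sigma[lower.tri(sigma)]
  r <- off[1]
  if (all(abs(off - r) < 1e-12) && r >= 0 && r < 1) r else NA_real_
}

# Exact crossing probability for exchangeable sigma with rho >= 0 via the
# one-factor representation Z_i = sqrt(rho) F + sqrt(1-rho) eps_i: given F
# the Z_i are iid, so the no-crossing probability is the classical iid
# order-statistic recursion with per-level exceedance probabilities
#   q_k(F) = Phibar((t_k - sqrt(rho) F)/sqrt(1-rho))
#          + Phibar((t_k + sqrt(rho) F)/sqrt(1-rho)),
# integrated over F by Gauss-Hermite quadrature. Exact up to quadrature
# error; reduces to the plain iid recursion at rho = 0.
crossing_prob_factor <- function(bounds, K, rho, nodes = 64L) {
  s <- sqrt(rho); r <- sqrt(1 - rho)
  gh <- if (rho > 0) gauss_hermite_norm(nodes) else list(x = 0, w = 1)
  total <- 0
  for (i in seq_along(gh$x)) {
    f <- gh$x[i]
    q <- ifelse(is.finite(bounds),
                norm_sf((pmax(bounds, 0) - s * f) / r) +
                norm_sf((pmax(bounds, 0) + s * f) / r), 0)
    total <- total + gh$w[i] * crossing_iid(q, K)
  }
  min(max(total, 0), 1)
}

# iid order-statistic boundary-crossing recursion (exact): per-level
# exceedance probabilities q_1 <= ... <= q_K for one variable
crossing_iid <- function(q, K) {
  f <- 1
  pcross <- 0
  q_prev <- 0
  for (k in seq_len(K)) {
    p_c <- if (q_prev < 1) (q[k] - q_prev) / (1 - q_prev) else 0
    p_c <- min(max(p_c, 0), 1)
    if (p_c == 0) {
      f <- c(f, 0)[seq_len(k)]
      q_prev <- max(q_prev, q[k])
      next
    }
    newf <- numeric(k)
    for (sp in seq_len(min(k, length(f))) - 1L) {
      fs <- f[sp + 1]
      if (fs <= 0) next
      nrem <- K - sp
      dmax <- k - 1L - sp
      pm <- stats::dbinom(0:nrem, nrem, p_c)
      keep <- 0:min(dmax, nrem)
      newf[sp + keep + 1] <- newf[sp + keep + 1] + fs * pm[keep + 1]
      if (nrem > dmax)
        pcross <- pcross + fs * sum(pm[(dmax + 2):(nrem + 1)])
    }
    f <- newf
    q_prev <- q[k]
  }
  pcross
}

crossing_prob <- function(bounds, sigma) {
  sigma <- as.matrix(sigma)
  K <- nrow(sigma)
  stopifnot(length(bounds) == K)
  rho <- exchangeable_rho(sigma)
  if (!is.na(rho))
    return(crossing_prob_factor(bounds, K, rho))
  q <- ifelse(is.finite(bounds), 2 * norm_sf(pmax(bounds, 0)), 0)
  f <- 1                      # no-crossing state distribution over s = 0..k-1
  pcross <- 0
  q_prev <- 0; m_prev <- 0; v_prev <- 0
  for (k in seq_len(K)) {
    sig2 <- if (is.finite(bounds[k]))
      var_exceedance_count(max(bounds[k], 0), sigma, 0) else 0
    p_c <- if (q_prev < 1) (q[k] - q_prev) / (1 - q_prev) else 0
    p_c <- min(max(p_c, 0), 1)
    if (p_c == 0) {           # unattainable or redundant level: carry state
      m_prev <- max(m_prev, K * q[k]); v_prev <- if (q[k] > q_prev) sig2 else v_prev
      q_prev <- max(q_prev, q[k])
      f <- c(f, 0)[seq_len(k)]
      next
    }
    # conditional dispersion matching the marginal variance of S(t_k)
    ER <- K - m_prev
    ERR1 <- v_prev + ER^2 - ER
    B <- p_c * (1 - p_c)
    A <- (1 - p_c)^2 * v_prev
    delta_c <- if (B > 0 && ERR1 > 1e-12) (sig2 - A - B * ER) / (B * ERR1) else 0
    newf <- numeric(k)
    for (sp in seq_len(min(k, length(f))) - 1L) {
      fs <- f[sp + 1]
      if (fs <= 0) next
      nrem <- K - sp
      dmax <- k - 1L - sp
      pm <- exp(debb_log_all(nrem, p_c, delta_c))
      keep <- 0:min(dmax, nrem)
      newf[sp + keep + 1] <- newf[sp + keep + 1] + fs * pm[keep + 1]
      if (nrem > dmax)
        pcross <- pcross + fs * sum(pm[(dmax + 2):(nrem + 1)])
    }
    f <- newf
    m_prev <- K * q[k]; v_prev <- sig2; q_prev <- q[k]
  }
  min(max(pcross, 0), 1)
}

# invert the GHC statistic: per-rank boundaries t_k with
# (k - 2K Phibar(t_k)) / sqrt(Var S(t_k)) = h, floored at t0
ghc_bounds <- function(h, K, sigma, t0 = 0) {
  vapply(seq_len(K), function(k) {
    g <- function(t) (k - 2 * K * norm_sf(t)) - h * sqrt(var_exceedance_count(t, sigma, 0))
    lo <- 1e-8
    if (g(lo) >= 0) return(max(lo, t0))          # crossed already at t ~ 0
    if (g(40) <= 0) return(Inf)                  # unattainable level
    max(uniroot(g, c(lo, 40), tol = 1e-11)$root, t0)
  }, 0)
}

# invert the GBJ statistic: smallest s with LR_k(s) = b for each rank k;
# ranks whose LR term cannot reach b get an infinite boundary
gbj_bounds <- function(b, K, sigma, k_range = "full") {
  kmax <- if (k_range == "half") max(1L, K %/% 2L) else K
  vapply(seq_len(K), function(k) {
    if (k > kmax) return(Inf)
    tlo <- qnorm(k / (2 * K), lower.tail = FALSE) + 1e-9
    g <- function(t) gbj_lr_term(t, k, K, sigma) - b
    if (g(tlo) >= 0) return(tlo)
    hi <- max(tlo + 1, 2)
    while (g(hi) < 0 && hi < 42) hi <- hi + 2
    if (g(hi) < 0) return(Inf)
    uniroot(g, c(tlo, hi), tol = 1e-11)$root
  }, 0)
}

#' Boundary-crossing p-value for supremum-based tests
#'
#' Shared analytic p-value engine. The observed statistic is inverted to a
#' non-increasing boundary vector (the smallest order-statistic values at
#' which the statistic reaches the observed value at each rank), and the
#' probability that the ordered `|Z|` cross the boundary anywhere is computed
#' under the exchangeable extended-beta-binomial approximation of the
#' exceedance counts. `HC` and `BJ` are the independence (`sigma = I`)
#' versions of `GHC` and `GBJ`; for `MinP` the observed statistic is the
#' Z-threshold `max|z|` and the boundary is flat.
#'
#' @param observed_stat observed statistic value.
#' @param statistic_kind one of `"GBJ"`, `"GHC"`, `"HC"`, `"BJ"`, `"MinP"`.
#' @param K number of traits.
#' @param sigma between-trait correlation matrix (ignored for `HC`/`BJ`,
#'   which use the identity).
#' @param t0 GHC truncation threshold (see [ghc_statistic()]).
#' @param k_range GBJ rank range (see [gbj_statistic()]).
#' @return p-value in `[0, 1]`, monotone non-increasing in `observed_stat`.
#' @export
crossing_pvalue <- function(observed_stat, statistic_kind = c("GBJ", "GHC", "HC", "BJ", "MinP"),
                            K, sigma = NULL, t0 = 0, k_range = "full") {
  statistic_kind <- match.arg(statistic_kind)
  if (is.na(observed_stat)) stop("observed_stat must be a number")
  if (statistic_kind %in% c("HC", "BJ") || is.null(sigma)) sigma <- diag(K)
  sigma <- as.matrix(sigma)
  stopifnot(nrow(sigma) == K)
  if (observed_stat == Inf) return(0)
  kind <- if (statistic_kind == "HC") "GHC" else if (statistic_kind == "BJ") "GBJ" else statistic_kind
  bounds <- switch(kind,
    GHC  = ghc_bounds(observed_stat, K, sigma, t0),
    GBJ  = {
      if (observed_stat <= 0) return(1)
      gbj_bounds(observed_stat, K, sigma, k_range)
    },
    MinP = {
      if (observed_stat < 0) return(1)
      rep(observed_stat, K)
    })
  crossing_prob(bounds, sigma)
}
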