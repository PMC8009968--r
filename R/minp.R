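# multivariate-normal machinery for the correlation-aware MinP test

# one-sided bivariate normal upper tail P(Z1 >= u, Z2 >= v), Mehler series
biv_tail <- function(u, v, rho, tol = 1e-18, nmax = 2000L) {
  if (abs(rho) > 0.9995) {
    S <- matrix(c(1, rho, rho, 1), 2)
    return(mvtnorm::pmvnorm(lower = c(u, v), upper = c(Inf, Inf), corr = S,
                            algorithm = mvtnorm::GenzBretz(abseps = 1e-12))[1])
  }
  acc <- norm_sf(u) * norm_sf(v)
  hpu <- 0; hcu <- 1; hpv <- 0; hcv <- 1
  rn <- 1
  for (n in seq_len(nmax)) {
    rn <- rn * rho
    term <- rn / n * (dnorm(u) * hcu) * (dnorm(v) * hcv)
    acc <- acc + term
    if (n > 20L && abs(term) < tol) break
    nu <- (u * hcu - sqrt(n - 1) * hpu) / sqrt(n)
    nv <- (v * hcv - sqrt(n - 1) * hpv) / sqrt(n)
    hpu <- hcu; hcu <- nu
    hpv <- hcv; hcv <- nv
  }
  max(acc, 0)
}

# m-variate upper tail P(Z_i >= a_i for all i) by conditioning on Z_1 and
# Gauss-Legendre quadrature; recursion bottoms out at the bivariate series.
# Deterministic and accurate deep in the tail (used for orders 3 and 4 of the
# inclusion-exclusion decomposition).
mvn_tail <- function(a, R, nodes = 64L) {
  m <- length(a)
  if (m == 1L) return(norm_sf(a))
  if (m == 2L) return(biv_tail(a[1], a[2], R[1, 2]))
  r1 <- R[-1, 1]
  C <- R[-1, -1] - tcrossprod(r1)
  sds <- sqrt(pmax(diag(C), 1e-12))
  Rc <- C / tcrossprod(sds)
  diag(Rc) <- 1
  gl_x <- gauss_legendre_nodes(nodes)
  lo <- a[1]; hi <- a[1] + 9
  x <- (gl_x$x + 1) / 2 * (hi - lo) + lo
  w <- gl_x$w * (hi - lo) / 2
  vals <- vapply(seq_along(x), function(i) {
    ac <- (a[-1] - r1 * x[i]) / sds
    dnorm(x[i]) * mvn_tail(ac, Rc, nodes)
  }, 0)
  sum(w * vals)
}

.gl_cache <- new.env(parent = emptyenv())
gauss_legendre_nodes <- function(n) {
  key <- as.character(n)
  if (!is.null(.gl_cache[[key]])) return(.gl_cache[[key]])
  # Golub-Welsch: eigen decomposition of the Jacobi matrix on [-1, 1]
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  res <- list(x = e$values, w = 2 * e$vectors[1, ]^2)
  .gl_cache[[key]] <- res
  res
}

# P(all K of |Z_i| >= c): sum over the 2^m sign orthants via mvn_tail
all_exceed_prob <- function(c0, sigma) {
  m <- nrow(sigma)
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), m)))
  tot <- 0
  for (i in seq_len(nrow(signs))) {
    D <- diag(signs[i, ], m)
    tot <- tot + mvn_tail(rep(c0, m), D %*% sigma %*% D)
  }
  tot
}

# MinP tail probability from the threshold c = max|z|:
# 1 - P(all |Z_k| < c) under MVN(0, sigma). For K <= 4 an exact
# inclusion-exclusion over subsets keeps full relative accuracy in extreme
# tails; for larger K the rectangle complement is computed by quasi-Monte
# Carlo (Genz-Bretz) with a fixed internal seed.
minp_from_threshold <- function(c0, sigma) {
  sigma <- as.matrix(sigma)
  K <- nrow(sigma)
  if (K == 1L) return(2 * norm_sf(c0))
  if (c0 <= 0) return(1)
  rho <- exchangeable_rho(sigma)
  if (!is.na(rho)) {
    # exact one-factor representation: P(all |Z_k| < c) integrates the
    # conditionally-iid rectangle over the shared factor
    if (rho == 0) return(1 - (1 - 2 * norm_sf(c0))^K)
    s <- sqrt(rho); r <- sqrt(1 - rho)
    gh <- gauss_hermite_norm(64L)
    q <- norm_sf((c0 - s * gh$x) / r) + norm_sf((c0 + s * gh$x) / r)
    return(min(max(1 - sum(gh$w * (1 - q)^K), 0), 1))
  }
  if (K <= 4L) {
    q1 <- 2 * norm_sf(c0)
    tot <- K * q1
    for (m in 2:K) {
      cm <- combn(K, m)
      sgn <- (-1)^(m - 1)
      for (i in seq_len(ncol(cm))) {
        idx <- cm[, i]
        if (m == 2L) {
          pm2 <- q1^2 + pair_exceedance_cov(c0, sigma[idx[1], idx[2]])
          tot <- tot - pm2
        } else {
          tot <- tot + sgn * all_exceed_prob(c0, sigma[idx, idx])
        }
      }
    }
    return(min(max(tot, 0), 1))
  }
  # larger K: truncated inclusion-exclusion in the far tail (error bounded by
  # the omitted fourth-order term), else quasi-Monte Carlo on the rectangle
  q1 <- 2 * norm_sf(c0)
  if (K * q1 < 2e-3) {
    tot <- K * q1
    for (i in seq_len(K - 1)) for (j in (i + 1):K)
      tot <- tot - (q1^2 + pair_exceedance_cov(c0, sigma[i, j]))
    cm <- combn(K, 3)
    for (i in seq_len(ncol(cm)))
      tot <- tot + all_exceed_prob(c0, sigma[cm[, i], cm[, i]])
    return(min(max(tot, 0), 1))
  }
  rect <- with_local_seed(20260920, {
    mvtnorm::pmvnorm(lower = rep(-c0, K), upper = rep(c0, K), sigma = sigma,
                     algorithm = mvtnorm::GenzBretz(abseps = 1e-5,
                                                    maxpts = 100000L))[1]
  })
  min(max(1 - rect, 0), 1)
}

#' Correlation-aware MinP p-value
#'
#' With `c = max_k |z_k|` (the Z-threshold of the smallest per-trait
#' two-sided p-value), returns `1 - P(all |Z_k| < c)` under
#' `Z ~ MVN(0, sigma)`. Satisfies the Bonferroni bounds
#' `min_k 2 Phibar(|z_k|) <= p <= K min_k 2 Phibar(|z_k|)`.
#'
#' @param z numeric vector of Z-scores.
#' @param sigma between-trait correlation matrix.
#' @return p-value in `[0, 1]`.
#' @export
minp_pvalue <- function(z, sigma) {
  check_z(z)
  minp_from_threshold(max(abs(z)), as.matrix(sigma))
}
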