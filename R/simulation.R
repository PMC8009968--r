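#' Define one simulation scenario
#'
#' A scenario is the tuple (K, sigma, mu, replicates, alpha, seed): Z-vectors
#' are drawn from MVN(mu, sigma); `mu = 0` gives a null (type-I error)
#' scenario, non-zero `mu` a power scenario.
#'
#' @param K number of traits.
#' @param sigma correlation matrix, or a scalar rho for the exchangeable
#'   matrix.
#' @param mu mean vector (scalar recycled to length K; default 0).
#' @param replicates number of Monte Carlo replicates.
#' @param alpha significance level in (0, 1).
#' @param seed RNG seed.
#' @return a `simulation_spec` list.
#' @export
simulation_spec <- function(K, sigma, mu = 0, replicates = 1000L,
                            alpha = 0.05, seed = 1L) {
  if (K < 2) stop("K must be >= 2")
  if (length(sigma) == 1L) sigma <- exchangeable_correlation(K, as.numeric(sigma))
  sigma <- trait_correlation(as.matrix(sigma))
  if (nrow(sigma) != K) stop("sigma dimension does not match K")
  mu <- rep_len(mu, K)
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  if (replicates < 1) stop("replicates must be >= 1")
  structure(list(K = as.integer(K), sigma = sigma, mu = mu,
                 replicates = as.integer(replicates), alpha = alpha,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Draw multivariate normal Z-vectors for a scenario
#'
#' `n` iid draws from MVN(mu, sigma) using the Cholesky factor of sigma
#' (with an eigenvalue fallback for semi-definite matrices); reproducible
#' given the spec's seed.
#'
#' @param spec a [simulation_spec()].
#' @param n number of draws (default `spec$replicates`).
#' @return n x K matrix.
#' @export
draw_z <- function(spec, n = spec$replicates) {
  sigma <- unclass(spec$sigma)
  ev <- eigen(sigma, symmetric = TRUE)
  if (min(ev$values) < -1e-8) stop("sigma is not positive semi-definite")
  L <- if (min(ev$values) > 1e-10) chol(sigma)
       else t(ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), spec$K))
  with_local_seed(spec$seed, {
    E <- matrix(rnorm(n * spec$K), n, spec$K)
    sweep(E %*% L, 2L, spec$mu, `+`)
  })
}

#' Empirical rejection rates of the four tests
#'
#' Draws `spec$replicates` Z-vectors, computes GBJ, GHC, MinP and OMNI
#' p-values using the true sigma of the scenario, and reports for each test
#' the fraction of p-values below `spec$alpha` together with its binomial
#' Monte-Carlo standard error. Under `mu = 0` this estimates the type-I
#' error; otherwise the power.
#'
#' @param spec a [simulation_spec()].
#' @param tests subset of `c("GBJ", "GHC", "MinP", "OMNI")`.
#' @param method p-value path passed to [multi_trait_pvalues()].
#' @return data.frame with columns `test`, `rate`, `mc_se`, `replicates`,
#'   `alpha`.
#' @export
empirical_rate <- function(spec, tests = c("GBJ", "GHC", "MinP", "OMNI"),
                           method = c("interpolate", "exact")) {
  method <- match.arg(method)
  tests <- match.arg(tests, several.ok = TRUE)
  Z <- draw_z(spec)
  P <- multi_trait_pvalues(Z, spec$sigma, method = method)
  cols <- c(GBJ = "p_gbj", GHC = "p_ghc", MinP = "p_minp", OMNI = "p_omni")
  # a level-1 test rejects everything; p-values can sit exactly at 1
  rate <- vapply(tests, function(tn)
    if (spec$alpha >= 1) 1 else mean(P[, cols[tn]] < spec$alpha), 0)
  data.frame(test = tests, rate = unname(rate),
             mc_se = sqrt(unname(rate) * (1 - unname(rate)) / spec$replicates),
             replicates = spec$replicates, alpha = spec$alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Run a grid of simulation scenarios
#'
#' Evaluates [empirical_rate()] over a table of exchangeable-correlation
#' scenarios. Each row names K, rho, the number of non-zero traits, the
#' common mean value of those traits, alpha and the replicate count; per-row
#' seeds are derived from `master_seed` so cells are reproducible and
#' independent.
#'
#' @param config data.frame with columns `K`, `rho`, `n_nonzero`, `mu_value`,
#'   and optionally `alpha` (default 0.05) and `replicates` (default 1000).
#' @param tests tests to run.
#' @param master_seed integer master seed.
#' @param method p-value path passed to [multi_trait_pvalues()].
#' @return long-format data.frame: one row per scenario x test with the rate
#'   and its Monte-Carlo standard error.
#' @export
scenario_grid <- function(config, tests = c("GBJ", "GHC", "MinP", "OMNI"),
                          master_seed = 1L, method = "interpolate") {
  if (!nrow(config))
    return(data.frame(K = integer(), rho = numeric(), n_nonzero = integer(),
                      mu_value = numeric(), alpha = numeric(), test = character(),
                      rate = numeric(), mc_se = numeric(), replicates = integer(),
                      stringsAsFactors = FALSE))
  out <- vector("list", nrow(config))
  for (i in seq_len(nrow(config))) {
    row <- config[i, ]
    alpha <- if ("alpha" %in% names(config)) row$alpha else 0.05
    reps <- if ("replicates" %in% names(config)) row$replicates else 1000L
    mu <- c(rep(row$mu_value, row$n_nonzero), rep(0, row$K - row$n_nonzero))
    spec <- simulation_spec(row$K, row$rho, mu, reps, alpha,
                            seed = (master_seed + 7919L * i) %% .Machine$integer.max)
    r <- empirical_rate(spec, tests, method = method)
    out[[i]] <- cbind(K = row$K, rho = row$rho, n_nonzero = row$n_nonzero,
                      mu_value = row$mu_value, r[, c("alpha", "test", "rate",
                                                     "mc_se", "replicates")])
  }
  do.call(rbind, out)
}
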