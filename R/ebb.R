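#' Extended beta-binomial parameters matched to a target variance
#'
#' The exceedance count `S(t)` of K correlated Z-scores is approximated by an
#' extended beta-binomial (EBB) distribution in the Prentice (1986)
#' parameterization: n trials, per-trial probability p, and a pairwise
#' correlation ("dispersion") parameter delta. Its variance is
#' `n p (1-p) (1 + (n-1) delta)`; `delta = 0` recovers the binomial, and
#' slightly negative delta (under-dispersion) is allowed within the EBB
#' validity region. The dispersion is chosen so the EBB variance equals
#' `target_var`; if the implied value falls outside the validity region it is
#' clamped to the nearest valid value and flagged.
#'
#' @param n_trials number of trials (number of traits K).
#' @param mean_prob per-trial exceedance probability in `(0, 1)`.
#' @param target_var variance to match (e.g. from [var_exceedance_count()]).
#' @return list with `n_trials`, `mean_prob`, `dispersion` and logical
#'   `clamped`.
#' @export
ebb_params <- function(n_trials, mean_prob, target_var) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (mean_prob <= 0 || mean_prob >= 1)
    stop("mean_prob must lie strictly in (0, 1)")
  base <- n_trials * mean_prob * (1 - mean_prob)
  delta <- if (n_trials > 1) (target_var / base - 1) / (n_trials - 1) else 0
  lim <- ebb_dispersion_bounds(n_trials, mean_prob)
  clamped <- delta < lim[1] || delta > lim[2]
  delta <- min(max(delta, lim[1]), lim[2])
  list(n_trials = as.integer(n_trials), mean_prob = mean_prob,
       dispersion = delta, clamped = clamped)
}

# validity region of the dispersion: every urn factor p + gamma*j and
# (1-p) + gamma*j, j = 0..n-1, must stay positive, with gamma = delta/(1-delta)
ebb_dispersion_bounds <- function(n, p) {
  if (n <= 1) return(c(0, 0))
  gmin <- -min(p, 1 - p) / (n - 1)
  dmin <- gmin / (1 + gmin)  # inverse of gamma = delta/(1-delta)
  c(dmin + 1e-12, 1 - 1e-9)
}

# log pmf of the EBB over x = 0..n, vectorized over x; scalar (n, p, delta).
# Parameters outside the validity region are clamped to its boundary.
debb_log_all <- function(n, p, delta) {
  if (n == 0L) return(0)
  if (p <= 0) return(c(0, rep(-Inf, n)))
  if (p >= 1) return(c(rep(-Inf, n), 0))
  lim <- ebb_dispersion_bounds(n, p)
  delta <- min(max(delta, lim[1]), lim[2])
  gam <- delta / (1 - delta)
  j <- seq_len(n) - 1
  cs <- c(0, cumsum(log(p + gam * j)))       # successes prefix
  cf <- c(0, cumsum(log(1 - p + gam * j)))   # failures prefix
  cd <- sum(log1p(gam * j))
  x <- 0:n
  lchoose(n, x) + cs[x + 1] + cf[n - x + 1] - cd
}

#' Extended beta-binomial probability mass function
#'
#' @param x integer count(s) in `0..n`.
#' @param n number of trials.
#' @param p per-trial probability.
#' @param dispersion pairwise correlation parameter (0 gives the binomial);
#'   values outside the EBB validity region are clamped to its boundary.
#' @param log return log probabilities?
#' @return pmf value(s).
#' @export
#' @examples
#' ebb_pmf(0:3, 3, 0.2, 0)          # binomial(3, 0.2)
#' sum(ebb_pmf(0:5, 5, 0.3, 0.1))   # 1
ebb_pmf <- function(x, n, p, dispersion = 0, log = FALSE) {
  if (any(x < 0 | x > n | x != floor(x)))
    stop("`x` must be integers in 0..n")
  lp <- debb_log_all(as.integer(n), p, dispersion)[x + 1]
  if (log) lp else exp(lp)
}

# log pmf at a fixed count x, vectorized over (p, delta) pairs (n scalar);
# used by the vectorized GBJ statistic over many replicates
debb_log_at <- function(x, n, p, delta) {
  lim_lo <- -pmin(p, 1 - p) / (n - 1)
  gam <- delta / (1 - delta)
  gam <- pmax(gam, lim_lo + 1e-15)
  acc <- rep(lchoose(n, x), length(p))
  if (x > 0) for (j in 0:(x - 1)) acc <- acc + log(p + gam * j)
  if (n - x > 0) for (j in 0:(n - x - 1)) acc <- acc + log(1 - p + gam * j)
  for (j in 0:(n - 1)) acc <- acc - log1p(gam * j)
  acc
}
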