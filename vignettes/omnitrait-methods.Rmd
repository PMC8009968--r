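---
title: "Methods: omnibus multi-phenotype association testing from summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: omnibus multi-phenotype association testing from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Model and assumptions

For one SNP and $K$ phenotypes, let $Z = (Z_1,\dots,Z_K)^\top$ collect the
per-trait GWAS Z-scores. In large samples $Z \sim \mathrm{MVN}(\mu, \Sigma)$,
where $\Sigma$ is the correlation of the test statistics across traits —
driven by phenotypic correlation and sample overlap, not by the SNP — and the
null of no association with any trait is $H_0: \mu = 0$. $\Sigma$ is shared
across SNPs and is estimated once as the Pearson correlation of the Z-score
columns over approximately independent SNPs (`estimate_trait_correlation()`).
Two assumptions matter in practice: the per-trait statistics are well
calibrated marginally (otherwise their inflation propagates), and the SNPs
used for estimating $\Sigma$ are representative nulls. The `null_z_cap`
option excludes strong-signal SNPs from the estimate; the default uses all
SNPs, since with millions of SNPs the handful of true signals moves the
estimate negligibly.

## The component tests

Write $S(t) = \sum_k 1\{|Z_k| \ge t\}$ (closed inequality) and
$\bar\Phi = 1 - \Phi$.

**GHC.** $\sup_{t \ge t_0} \{S(t) - 2K\bar\Phi(t)\}/\sqrt{\widehat{\mathrm{var}} S(t)}$.
The numerator is piecewise constant between observed order statistics of
$|z|$ and increases within each piece as $t$ grows, so the supremum is
attained on the finite candidate set $\{|z|_{(k)}\}$ and is evaluated there.
$\mathrm{Var}\,S(t)$ sums the $K$ Bernoulli variances and all pairwise
indicator covariances, computed by the Mehler (Hermite-polynomial) expansion
of the bivariate normal density; each series term is a perfect square, so
the expansion keeps full relative accuracy deep in the tail. The truncation
point $t_0$ defaults to 0 and is user-overridable.

**GBJ.** For rank $k$, the observed order statistic $s = |z|_{(K-k+1)}$
implies a common mean shift $\hat\mu_{k,K} \ge 0$ solving
$k/K = \bar\Phi(s - \mu) + \bar\Phi(s + \mu)$ (`solve_mu_hat()`, bracketed
root-finding on $[0, s+10]$, tolerance $10^{-10}$). The statistic is the
maximum over $k$ of
$\log \Pr\{S(s) = k \mid \mu = \hat\mu\} - \log \Pr\{S(s) = k \mid \mu = 0\}$,
each probability from an extended beta-binomial (EBB, Prentice
parameterization) with per-trial probability $\bar\Phi(s-\mu)+\bar\Phi(s+\mu)$
and dispersion matched so the EBB variance equals $\mathrm{Var}\,S(s)$ under
the respective mean. Terms carry the indicator $2\bar\Phi(s) < k/K$ and the
maximum is floored at 0. Two boundary conventions were genuinely open:

* *Rank range.* The statistic defaults to ranks $1..K$, with a switch for
  $1..\lfloor K/2 \rfloor$. The indicator already silences uninformative
  ranks, so the full range is the safer default.
* *The $k = K$ term.* The defining equation targets $k/K = 1$, which no
  finite shift attains; `solve_mu_hat()` returns 0 whenever no positive root
  exists, which makes the $k=K$ likelihood-ratio term vanish identically.
  This convention keeps the statistic finite and, because the term can then
  never contribute a boundary crossing, makes the analytic p-value of the
  remaining ranks essentially exact (the corresponding crossing level is
  dropped rather than approximated).

**MinP.** $p = 1 - \Pr(\max_k |Z_k| < c)$ at $c = \max_k |z_k|$. For
exchangeable $\Sigma$ the rectangle is a one-dimensional integral over the
shared Gaussian factor (exact); for $K \le 4$ it is an inclusion–exclusion
over subsets with bivariate terms from the Mehler series and higher orders
from a deterministic conditioned-quadrature tail routine, which preserves
relative accuracy at genome-wide thresholds; for larger non-exchangeable
$K$ a quasi-Monte-Carlo rectangle (Genz–Bretz, fixed internal seed,
absolute tolerance $10^{-5}$) is used at moderate thresholds and the
truncated inclusion–exclusion (error bounded by the omitted fourth-order
term) in the far tail.

**OMNI.** The equal-weight Cauchy combination of the three p-values,
$\mathrm{OMNI} = \tfrac13\sum \tan\{(0.5-p)\pi\}$,
$p_{\mathrm{OMNI}} = \tfrac12 - \arctan(\mathrm{OMNI})/\pi$. Its null
validity does not require knowing the dependence among the components. For
$p < 10^{-16}$ the transform switches to its asymptote $1/(p\pi)$ and for
large combined statistics the p-value to $1/(\pi T)$, avoiding overflow
while preserving relative accuracy; combining identical p-values returns
them exactly.

## Analytic p-values: the boundary-crossing engine

Each supremum statistic, inverted rank by rank, yields non-increasing
thresholds $t_1 \ge \dots \ge t_K$ such that the statistic reaches its
observed value when $|Z|_{(K-k+1)} = t_k$; the p-value is
$\Pr(\exists k: |Z|_{(K-k+1)} \ge t_k)$, i.e. one minus the probability that
the exceedance counts satisfy $S(t_k) \le k-1$ for all $k$. Ranks whose
likelihood-ratio term cannot reach the observed value receive an infinite
threshold and contribute nothing. Two computational routes:

* **Exchangeable $\Sigma$ with $\rho \ge 0$ (exact).** Writing
  $Z_i = \sqrt{\rho}\,F + \sqrt{1-\rho}\,\varepsilon_i$, the $Z_i$ are iid
  given the shared factor $F$, so the no-crossing probability is the
  classical iid order-statistic recursion with per-level probabilities
  $q_k(F)$, integrated over $F$ with 64-point Gauss–Hermite quadrature.
  This covers the identity matrix and every exchangeable simulation design
  with quadrature-level accuracy at any $K$.
* **General $\Sigma$ (approximate).** The counts
  $S(t_1) \le \dots \le S(t_K)$ are treated as a Markov chain whose
  increments, conditional on $S(t_{k-1}) = s$, are EBB over the $K-s$
  remaining traits with the exact conditional success probability
  $(q_k - q_{k-1})/(1 - q_{k-1})$ and a dispersion chosen so the implied
  marginal variance of $S(t_k)$ matches $\mathrm{Var}\,S(t_k)$ under
  $\Sigma$. At $\Sigma = I$ the dispersion is zero and the recursion is
  exact. Crossing mass is accumulated level by level from EBB upper tails,
  which keeps relative accuracy for p-values down to $10^{-300}$
  (reported values below that are floored and flagged).

The engine is validated against Monte-Carlo exceedance estimates of the
statistics (unit tests, $10^5$ draws, three binomial standard errors) and,
for the general-$\Sigma$ route at $K = 3$, against semi-exact
inclusion–exclusion computations of the crossing probability.

The GBJ p-value inherits an atom at 1: with positive probability no
likelihood-ratio term is active and the statistic is exactly 0. P-values are
therefore uniform on the continuous range and conservative at the atom; the
uniformity tests condition on $p < 0.5$.

## Simulation suite

`simulation_spec()` fixes (K, $\Sigma$, $\mu$, replicates, $\alpha$, seed);
`draw_z()` draws MVN vectors via the Cholesky factor; `empirical_rate()`
reports rejection proportions with binomial standard errors, using the true
$\Sigma$ in the tests (estimation can be exercised separately through the
IO module). Because each analytic p-value is a fixed monotone function of
its statistic given $\Sigma$, the default path evaluates the exact p-value
on a quantile grid of the observed statistics (up to 256 points, fewer for
small runs) and interpolates log p linearly between grid points; the
interpolation error is orders of magnitude below Monte-Carlo noise at the
replicate counts used ($10^3$–$10^4$), and `method = "exact"` disables it.
The generator emulates exactly the distributional setting of the method —
MVN scores with a known, SNP-independent $\Sigma$. It does not emulate LD
between SNPs, miscalibrated per-trait statistics, or estimation error in
$\Sigma$; passing simulations therefore certify the tests' calibration and
power under the model, not robustness to violations of it.

Default scenario sizes follow the published study design: exchangeable
$\rho \in \{0.1, 0.3, 0.5\}$ at $K \in \{2, 4, 10\}$ for type-I error
(replicates $10^3$–$10^4$ at $\alpha \ge 0.01$ here; the rarest published
levels used $10^6$ replicates and are reproduced at reduced scale), mean
shifts of magnitude 2 for power, and the two printed $K=3$ correlation
structures. One printed matrix is asymmetric in its source (its (1,3) and
(3,1) entries disagree at 0.30 vs 0.50); it is used here as the symmetric
matrix with 0.50 in that pair, reading the lone 0.50 as the intended
heterogeneous entry.

## Numerical choices

* Hermite series: terms to machine-precision convergence (cap 1500);
  $|\rho| > 0.9995$ switches to degenerate closed forms ($|\rho| = 1$ pairs
  are permitted, where the two indicators coincide).
* Sign conventions: under a common mean shift the pairwise indicator
  covariance is not an even function of $\rho$, yet allele coding — hence
  the sign of each trait's Z-scores and of the correlations involving it —
  is arbitrary. The implementation uses the even part in $\rho$ (the
  covariance averaged over the pair's two sign conventions), which makes
  every test exactly invariant to trait sign flips; the numerical effect is
  below $10^{-3}$ relative and vanishes at $\mu = 0$.
* Root-finding: `uniroot` at tolerance $10^{-11}$ for boundary inversion;
  64-step bisection in the vectorized paths. Ties among $|z|$ are handled
  by counting all coincident values in $S(t)$.
* EBB validity: the dispersion is clamped to the Prentice region (all urn
  factors positive) and flagged; the pmf then remains a proper
  distribution.
* Degenerate inputs: all-zero $z$ gives statistic 0 at $t = 0$ for GHC
  (with a warning if $t_0$ excludes every candidate); statistics below
  their attainable minimum return p-value 1; $K = 1$ reduces every test to
  the two-sided normal p-value.
* Allele harmonization: swapped and strand-flipped pairs negate or keep
  $z$ deterministically; palindromic SNPs are dropped by default since
  strand cannot be resolved from summary data alone.
* Estimated $\hat\Sigma$ is symmetrized, unit-diagonal, and eigenvalue-
  clipped to the nearest PSD correlation matrix when sampling noise makes
  it indefinite.

## Known limitations

* The general-$\Sigma$ crossing probability is an approximation; its
  accuracy degrades slowly with strong non-exchangeable correlation and is
  weakest for deep-tail p-values at large $K$ with heterogeneous strong
  correlations (relative, not absolute, deviations of a few percent at
  moderate p in the validated range).
* LD pruning is delegated: the package consumes a whitelist of independent
  SNPs rather than computing $r^2$ from genotypes.
* Sample-overlap corrections beyond the sample-correlation estimator of
  $\Sigma$, SNP-set (multi-variant) extensions, and comparator tests from
  other families are out of scope.
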