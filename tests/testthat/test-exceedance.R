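test_that("exceedance_count counts closed-threshold exceedances", {
  expect_identical(exceedance_count(c(0, 0), 1), 0L)
  expect_identical(exceedance_count(c(2, -3, 0.5), 1.5), 2L)
  expect_identical(exceedance_count(c(1, 1), 1), 2L)  # boundary counts
  expect_error(exceedance_count(c(1, 2), -0.1), "non-negative")
  expect_error(exceedance_count(c(1, Inf), 1), "finite")
})

test_that("pair_exceedance_cov matches independence, degeneracy and quadrature", {
  expect_equal(pair_exceedance_cov(1, 0), 0)
  q <- 2 * pnorm(1, lower.tail = FALSE)
  expect_equal(pair_exceedance_cov(1, 1), q * (1 - q), tolerance = 1e-12)
  expect_equal(pair_exceedance_cov(1, -1), q * (1 - q), tolerance = 1e-12)
  expect_error(pair_exceedance_cov(1, 1.5), "\\[-1, 1\\]")

  # adaptive 2-D quadrature oracle over the four tail rectangles at t=2, rho=0.5
  skip_if_not_installed("pracma")
  rho <- 0.5
  dens <- function(x, y)
    exp(-(x^2 - 2 * rho * x * y + y^2) / (2 * (1 - rho^2))) /
      (2 * pi * sqrt(1 - rho^2))
  p11 <- pracma::integral2(dens, 2, 9, 2, 9)$Q +
    pracma::integral2(dens, 2, 9, -9, -2)$Q +
    pracma::integral2(dens, -9, -2, 2, 9)$Q +
    pracma::integral2(dens, -9, -2, -9, -2)$Q
  q2 <- 2 * pnorm(2, lower.tail = FALSE)
  expect_lt(abs(pair_exceedance_cov(2, 0.5) - (p11 - q2^2)), 1e-8)
})

test_that("pair covariance is an even function of rho", {
  for (t in c(0.5, 1.5, 3)) for (r in c(0.2, 0.45, 0.8))
    expect_equal(pair_exceedance_cov(t, r), pair_exceedance_cov(t, -r),
                 tolerance = 1e-12)
})

test_that("var_exceedance_count: closed form, vanishing tail, MC oracle", {
  q <- 2 * pnorm(1, lower.tail = FALSE)
  expect_equal(var_exceedance_count(1, diag(5)), 5 * q * (1 - q),
               tolerance = 1e-12)
  expect_lt(var_exceedance_count(10, exchangeable_correlation(4, 0.5)), 1e-10)
  # frozen 1e7-draw Monte Carlo oracle for K=3, exchangeable rho=0.3, t=1.5
  # (value 0.388519, three oracle standard errors ~ 1e-3)
  expect_equal(var_exceedance_count(1.5, exchangeable_correlation(3, 0.3)),
               0.388519, tolerance = 1e-3)
})

test_that("variance is invariant under trait sign flips", {
  sig <- sigma2_matrix()
  D <- diag(c(1, -1, 1))
  flipped <- D %*% sig %*% D
  for (t in c(0.5, 2, 4))
    expect_equal(var_exceedance_count(t, sig), var_exceedance_count(t, flipped),
                 tolerance = 1e-12)
})

test_that("trait_correlation validates its invariants", {
  expect_error(trait_correlation(matrix(c(1, 0.5, 0.2, 1), 2)), "symmetric")
  expect_error(trait_correlation(matrix(c(2, 0, 0, 1), 2)), "diagonal")
  expect_error(trait_correlation(matrix(c(1, -0.9, -0.9,
                                          -0.9, 1, -0.9,
                                          -0.9, -0.9, 1), 3)),
               "positive semi-definite")
  expect_s3_class(exchangeable_correlation(4, 0.3), "trait_correlation")
  expect_error(exchangeable_correlation(4, -0.9), "exchangeable")
})
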