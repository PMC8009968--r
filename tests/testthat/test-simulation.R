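test_that("draw_z is reproducible and matches its target moments", {
  spec <- simulation_spec(2, 0.3, mu = 0, replicates = 1e5, seed = 21)
  Z1 <- draw_z(spec)
  Z2 <- draw_z(spec)
  expect_identical(Z1, Z2)
  expect_lt(abs(cor(Z1[, 1], Z1[, 2]) - 0.3), 0.01)
  spec2 <- simulation_spec(2, 0.3, mu = 2, replicates = 1e4, seed = 22)
  Zm <- draw_z(spec2)
  expect_lt(max(abs(colMeans(Zm) - 2)), 3 / sqrt(1e4))
})

test_that("empirical_rate is degenerate at alpha = 1 and validates inputs", {
  r <- empirical_rate(simulation_spec(2, 0.1, 0, 50, alpha = 1, seed = 1))
  expect_true(all(r$rate == 1))
  expect_equal(r$mc_se, sqrt(r$rate * (1 - r$rate) / r$replicates))
  expect_error(simulation_spec(1, 0.1, 0, 10), "K must be")
  expect_error(simulation_spec(3, 0.1, 0, 10, alpha = 0), "alpha")
})

test_that("null p-values are uniform (KS on the continuous range)", {
  # GBJ p-values carry an atom at 1 (the event that no likelihood-ratio term
  # is active), so uniformity is checked conditionally on p < 0.5 for all
  # tests: under H0, P(p <= x | p < c) = x/c on the continuous part
  spec <- simulation_spec(4, 0.3, 0, 2000, seed = 33)
  P <- multi_trait_pvalues(draw_z(spec), spec$sigma)
  for (cn in colnames(P)) {
    ps <- P[, cn]
    sub <- ps[ps < 0.5] / 0.5
    expect_gt(suppressWarnings(ks.test(sub, "punif")$p.value), 0.01)
  }
})

test_that("power increases with the common signal size", {
  s1 <- empirical_rate(simulation_spec(3, 0.3, c(1, 1, 0), 400, seed = 8),
                       tests = "GBJ")
  s2 <- empirical_rate(simulation_spec(3, 0.3, c(2, 2, 0), 400, seed = 8),
                       tests = "GBJ")
  expect_gt(s2$rate, s1$rate - 3 * sqrt(s1$mc_se^2 + s2$mc_se^2))
  expect_gt(s2$rate, s1$rate)  # at these sizes the ordering is clear-cut
})

test_that("scenario_grid reproduces the sparsity ordering of the tests", {
  cfg <- data.frame(K = 10, rho = 0.3, n_nonzero = c(1L, 9L), mu_value = 2,
                    alpha = 0.05, replicates = 400L)
  g <- scenario_grid(cfg, master_seed = 9)
  expect_equal(nrow(g), 8L)
  r1 <- g[g$n_nonzero == 1, ]
  r9 <- g[g$n_nonzero == 9, ]
  se <- function(d) sqrt(sum(d$mc_se^2))
  # extreme sparsity favors MinP over GBJ; dense signals the reverse
  expect_gt(r1$rate[r1$test == "MinP"],
            r1$rate[r1$test == "GBJ"] - 3 * se(r1))
  expect_gt(r9$rate[r9$test == "GBJ"],
            r9$rate[r9$test == "MinP"] - 3 * se(r9))
  expect_equal(nrow(scenario_grid(cfg[0, ])), 0L)
})

test_that("OMNI tracks the best component test in Table-2-style scenarios", {
  for (cs in list(list(s = sigma1_matrix(), mu = c(-2, 2, 2)),
                  list(s = sigma2_matrix(), mu = c(2, -2, 2)))) {
    r <- empirical_rate(simulation_spec(3, cs$s, cs$mu, 400, seed = 14))
    best <- max(r$rate[r$test != "OMNI"])
    omni <- r$rate[r$test == "OMNI"]
    expect_gt(omni, best - 0.1 - 3 * max(r$mc_se))
  }
})
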