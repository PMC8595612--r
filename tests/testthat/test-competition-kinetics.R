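test_that("initial rate is the linear-window slope", {
  tt <- seq(0, 60, by = 2)
  r <- initial_rate(tt, (100 - 0.5 * tt) * 1e-6)
  expect_equal(r$v0, 0.5e-6, tolerance = 1e-12)
  expect_equal(r$r_squared, 1, tolerance = 1e-9)
  expect_equal(initial_rate(tt, rep(1e-4, length(tt)))$v0, 0)
  # curvature bias of an endpoint window on an exponential is small
  ce <- 100e-6 * exp(-0.005 * tt)
  re <- suppressWarnings(initial_rate(tt, ce))
  true_v0 <- 0.005 * 100e-6
  expect_lt(abs(re$v0 - true_v0) / true_v0, 0.08)
  # and agrees with the analytic derivative at the window midpoint within 5%
  v_mid <- 0.005 * 100e-6 * exp(-0.005 * 15)
  expect_lt(abs(re$v0 - v_mid) / v_mid, 0.05)
  expect_error(initial_rate(c(0, 40, 50, 60), (100 - 0.5 * c(0, 40, 50, 60)) * 1e-6),
               "invalid window")
})

test_that("initial-rate series gives the bimolecular constant", {
  S <- c(10, 20, 40) * 1e-6
  k <- bimolecular_k_from_rates(S, 4.2e-3 * S, enzyme_conc = 0.2e-6)
  expect_equal(k$value, 2.1e4, tolerance = 1e-9)
  k2 <- bimolecular_k_from_rates(S, 3.6e-3 * S, enzyme_conc = 0.2e-6)
  expect_equal(k2$value, 1.8e4, tolerance = 1e-9)
  expect_equal(bimolecular_k_from_rates(S, rep(0, 3), 0.2e-6)$value, 0)
  expect_error(bimolecular_k_from_rates(S, 4.2e-3 * S, 0), "positive")
})

test_that("suppression inversion is exact at symmetry and directional", {
  # f = 0.5 with equal concentrations returns the reference constant
  for (kref in c(1e4, 2e7)) {
    k <- competitor_k_from_suppression(0.5, kref, 4e-6, 4e-6)
    expect_equal(k$value, kref, tolerance = 1e-12)
  }
  # printed-input inversion of the oxidant-partitioning observation
  k <- competitor_k_from_suppression(0.12, 2e7, 4e-6, 20e-6)
  expect_equal(k$value, 0.12 / 0.88 * 2e7 * 4 / 20, tolerance = 1e-12)
  expect_equal(k$value, 5.4545e5, tolerance = 1e-4)
  # no suppression leaves the constant below detection: upper-bound flag
  kb <- competitor_k_from_suppression(1, 2e7, 4e-6, 20e-6)
  expect_true("upper_bound" %in% kb$flags)
  expect_error(competitor_k_from_suppression(0, 2e7, 4e-6, 20e-6), "rejected")
})

test_that("suppression inversion is monotone in the observed fraction", {
  fs <- seq(0.05, 0.95, by = 0.05)
  k_comp <- vapply(fs, function(f) {
    competitor_k_from_suppression(f, 2e7, 4e-6, 20e-6,
                                  monitored = "competitor")$value
  }, numeric(1))
  expect_true(all(diff(k_comp) > 0))
  k_ref_mode <- vapply(fs, function(f) {
    competitor_k_from_suppression(f, 2e7, 4e-6, 20e-6,
                                  monitored = "reference")$value
  }, numeric(1))
  expect_true(all(diff(k_ref_mode) < 0))
})

test_that("delta-method error propagation scales with the fraction uncertainty", {
  k1 <- competitor_k_from_suppression(0.12, 2e7, 4e-6, 20e-6,
                                      fraction_se = 0.01)
  k2 <- competitor_k_from_suppression(0.12, 2e7, 4e-6, 20e-6,
                                      fraction_se = 0.02)
  expect_equal(k2$se / k1$se, 2, tolerance = 1e-9)
  expect_equal(k1$se, 2e7 * 4 / 20 / (1 - 0.12)^2 * 0.01, tolerance = 1e-9)
})

test_that("depletion-aware inversion solves the conservation relation", {
  # printed observation: 0.24 uM product of 2 uM oxidant
  k <- refine_by_depletion(0.24e-6, 2e-6, 2e7, 4e-6, 20e-6)
  expect_equal(k$value, 4.1e5, tolerance = 0.02)
  # the returned constant satisfies the relation it was solved from
  resid <- 0.24e-6 +
    4e-6 * (1 - exp(-2e7 * 0.24e-6 / (k$value * 20e-6))) - 2e-6
  expect_lt(abs(resid), 1e-12)
  # zero product means no detectable competitor channel
  expect_equal(refine_by_depletion(0, 2e-6, 2e7, 4e-6, 20e-6)$value, 0)
  expect_error(refine_by_depletion(2.5e-6, 2e-6, 2e7, 4e-6, 20e-6),
               "impossible")
})

test_that("depletion inversion reduces to simple suppression for large reservoirs", {
  # with a huge reference reservoir its fractional consumption vanishes and
  # the two estimators agree
  k_true <- 3e5; k_ref <- 2e7; comp <- 20e-6
  p0 <- 4e-3  # 1000x the oxidant
  h0 <- 2e-6
  # forward: fraction through the competitor channel is constant
  f <- k_true * comp / (k_true * comp + k_ref * p0)
  prod <- f * h0
  k_simple <- competitor_k_from_suppression(f, k_ref, p0, comp)$value
  k_depl <- refine_by_depletion(prod, h0, k_ref, p0, comp)$value
  expect_equal(k_simple, k_true, tolerance = 1e-9)
  expect_equal(k_depl, k_true, tolerance = 0.01)
})

test_that("forward simulation and depletion inversion are mutually consistent", {
  # yields generated by the mass-action network at known constants invert
  # back to those constants across four decades
  for (k_true in c(1e3, 1e4, 1e5, 1e6, 1e7)) {
    dat <- gen_competition_dataset(k_true)
    k_rec <- refine_by_depletion(mean(dat$product_conc), 2e-6, 2e7, 4e-6,
                                 20e-6)$value
    expect_lt(abs(k_rec - k_true) / k_true, 0.02)
  }
})

test_that("sub-noise-floor suppression returns a bound at or above the truth", {
  # a competitor too slow to suppress the signal measurably: the flagged
  # bound must not understate it
  k_true <- 50   # yields f ~ 1 for the reference channel
  f_obs <- 1     # suppression below the measurement floor rounds to 1
  kb <- competitor_k_from_suppression(f_obs, 2e7, 4e-6, 20e-6,
                                      monitored = "reference")
  expect_true("upper_bound" %in% kb$flags)
  expect_gte(kb$value, k_true)
})
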