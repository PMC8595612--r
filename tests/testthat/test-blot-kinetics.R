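test_that("dimer-to-total ratio covers the redox-state readout", {
  expect_equal(dimer_total_ratio(50, 50), 0.5)
  expect_equal(dimer_total_ratio(80, 0), 0)
  expect_equal(dimer_total_ratio(10, 30), 0.75)
  expect_error(dimer_total_ratio(0, 0), "unquantifiable")
})

test_that("exponential fit recovers a known decay constant", {
  t <- c(0, 5, 10, 20, 30)
  fit <- fit_monomer_decay(t, 100 * exp(-0.1 * t))
  expect_equal(fit$k_obs, 0.1, tolerance = 1e-6)
  expect_equal(fit$offset, 0, tolerance = 1e-4)
  # with a genuine plateau
  fit2 <- fit_monomer_decay(t, 70 * exp(-0.1 * t) + 30)
  expect_equal(fit2$k_obs, 0.1, tolerance = 1e-6)
  expect_equal(fit2$offset, 30, tolerance = 1e-3)
  # constant signal is degenerate, k_obs = 0
  fit3 <- fit_monomer_decay(t, rep(100, 5))
  expect_equal(fit3$k_obs, 0)
  expect_true("degenerate" %in% fit3$flags)
  expect_error(fit_monomer_decay(c(0, 0, 0), c(1, 2, 3)), "distinct")
})

test_that("noisy decay still brackets the generating constant in its CI", {
  t <- seq(0, 30, by = 3)
  set.seed(7)
  n_rep <- 200L
  tq <- qt(0.975, df = length(t) - 3L)  # small-sample CI from the t quantile
  covered <- 0L
  for (i in seq_len(n_rep)) {
    y <- 100 * exp(-0.1 * t) * exp(rnorm(length(t), 0, 0.05))
    fit <- fit_monomer_decay(t, y)
    ci <- fit$k_obs + c(-tq, tq) * fit$se
    if (ci[1] <= 0.1 && 0.1 <= ci[2]) covered <- covered + 1L
  }
  expect_gte(covered / n_rep, 0.9)
})

test_that("k_obs regression gives the second-order constant with background intercept", {
  conc <- c(5, 10, 20, 40) * 1e-6
  k <- second_order_from_kobs(conc, 3.8e3 * conc)
  expect_equal(k$value, 3.8e3, tolerance = 1e-9)
  expect_equal(k$details$intercept, 0, tolerance = 1e-12)
  # flat k_obs means no reaction
  expect_equal(second_order_from_kobs(conc, rep(0, 4))$value, 0)
  # trans-type design
  k2 <- second_order_from_kobs(c(2, 8, 16) * 1e-6, c(0.023, 0.089, 0.177))
  expect_equal(k2$value, 1.1e4, tolerance = 0.02)
  expect_error(second_order_from_kobs(c(1, 2) * 1e-6, c(1, 2)), "insufficient")
})

test_that("regression slope is invariant to rescaling the intensity scale", {
  # intensity rescaling changes neither k_obs nor the slope
  t <- c(0, 5, 10, 20, 30, 40)
  concs <- c(5, 10, 20, 40) * 1e-6
  for (s in c(0.2, 7)) {
    ks <- vapply(concs, function(w) {
      y <- 100 * exp(-3.8e3 * w * t)
      fit_monomer_decay(t, s * y)$k_obs
    }, numeric(1))
    k <- second_order_from_kobs(concs, ks)
    expect_equal(k$value, 3.8e3, tolerance = 1e-5)
  }
})

test_that("single-point estimate matches arithmetic and flags strained regimes", {
  k <- single_point_k(0.02, 20e-6, 20e-6, 10)
  expect_equal(k$value, 100)
  expect_equal(single_point_k(0, 20e-6, 20e-6, 10)$value, 0)
  k2 <- single_point_k(0.2, 20e-6, 20e-6, 10)
  expect_equal(k2$value, 1e3)
  expect_length(k2$flags, 0)
  expect_true("unreliable" %in% single_point_k(0.3, 20e-6, 20e-6, 10)$flags)
  expect_error(single_point_k(1, 20e-6, 20e-6, 10), "complete conversion")
})

test_that("single-point estimate converges to the integrated equal-concentration law", {
  # oracle: integrated second-order law at equal concentrations gives the
  # dimer fraction f = 1 - C(t)/C0 produced by a true constant k
  c0 <- 20e-6; t_rxn <- 10
  for (k_true in c(50, 100, 250)) {
    f <- 1 - second_order_equal(c0, k_true, t_rxn) / c0
    if (f > 0.05) next
    k_est <- single_point_k(f, c0, c0, t_rxn)$value
    expect_lt(abs(k_est - k_true) / k_true, 0.05)
  }
  # the estimate approaches the truth from below as f -> 0
  f_small <- 1 - second_order_equal(c0, 5, t_rxn) / c0
  expect_lt(abs(single_point_k(f_small, c0, c0, t_rxn)$value - 5) / 5, 0.002)
})

test_that("standard-curve quantification converts intensity to fmol per ug", {
  res <- quantify_from_standard_curve(100, slope = 10, molecular_weight = 22000,
                                      tissue_loaded_ug = 20)
  expect_equal(res$fmol_per_ug, 10 * 1e6 / 22000 / 20)
  expect_equal(quantify_from_standard_curve(0, 10, 0, 22000, 20)$fmol_per_ug, 0)
  res2 <- quantify_from_standard_curve(50, slope = 10,
                                       molecular_weight = 25000,
                                       tissue_loaded_ug = 10)
  expect_equal(res2$fmol_per_ug, 20)
  expect_true(quantify_from_standard_curve(500, 10, 0, 25000, 10,
                                           calibrated_range = c(0, 100))$extrapolated)
  expect_error(quantify_from_standard_curve(10, -1, 0, 25000, 10), "slope")
})

test_that("the full blot pipeline recovers generating constants from clamped-oxidant lanes", {
  # pseudo-first-order generation satisfies the fitting model exactly
  tab <- gen_blot_timecourse(3.8e3, 5e-6, c(5, 10, 20, 40) * 1e-6,
                             times = c(0, 5, 10, 20, 30, 40),
                             pseudo_first_order = TRUE)
  k <- suppressWarnings(blot_rate_constant(tab, enzyme_conc = 5e-6))
  expect_equal(k$value, 3.8e3, tolerance = 1e-3)
  # low oxidant excess over the enzyme triggers the validity warning
  expect_warning(blot_rate_constant(tab, enzyme_conc = 5e-6), "4-fold")
})

test_that("noisy replicate pipeline keeps the generating constant inside its CI", {
  hits <- 0L
  n_rep <- 40L
  for (i in seq_len(n_rep)) {
    tab <- gen_blot_timecourse(3.8e3, 5e-6, c(5, 10, 20, 40) * 1e-6,
                               times = c(0, 5, 10, 20, 30, 40),
                               pseudo_first_order = TRUE,
                               noise_cv = 0.05, seed = 1000 + i)
    k <- suppressWarnings(blot_rate_constant(tab, enzyme_conc = 5e-6))
    tq <- qt(0.975, df = 2)  # 4 concentrations, 2 regression parameters
    ci <- k$value + c(-tq, tq) * k$se
    if (ci[1] <= 3.8e3 && 3.8e3 <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
})
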