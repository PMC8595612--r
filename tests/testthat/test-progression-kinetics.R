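test_that("substrate trace inverts the NADPH absorbance bookkeeping", {
  t <- 0:10
  rooh0 <- 2e-5
  # flat absorbance means no consumption
  tr <- substrate_trace(t, rep(1, 11), rooh0)
  expect_equal(tr$conc, rep(rooh0, 11))
  # a drop of 0.1244 AU is 20 uM consumed: substrate exhausted
  a <- c(rep(1, 10), 1 - 0.1244)
  tr2 <- substrate_trace(t, a, rooh0)
  expect_equal(tr2$conc[11], 0)
  # exponential absorbance decay maps to exponential substrate decay
  tt <- 0:60
  a3 <- 1 - 6220 * rooh0 * (1 - exp(-0.05 * tt))
  tr3 <- substrate_trace(tt, a3, rooh0)
  expect_equal(tr3$conc, rooh0 * exp(-0.05 * tt), tolerance = 1e-10)
  expect_error(substrate_trace(t, seq(1, 1.2, length.out = 11), rooh0),
               "increases")
})

test_that("log-linear window slope returns the pseudo-first-order constant", {
  tt <- 0:60
  conc <- 2e-5 * exp(-0.05 * tt)
  res <- pseudo_first_order(tt, conc)
  expect_equal(res$k_prime, 0.05, tolerance = 1e-9)
  expect_equal(res$r_squared, 1, tolerance = 1e-9)
  # constant trace: zero slope
  expect_equal(pseudo_first_order(tt, rep(1e-5, 61))$k_prime, 0)
  # invariance to uniform scaling of the trace
  expect_equal(pseudo_first_order(tt, 100 * conc)$k_prime, 0.05,
               tolerance = 1e-9)
  # noisy trace keeps the truth inside the 95% CI
  set.seed(11)
  noisy <- conc * exp(rnorm(61, 0, 0.03))
  resn <- pseudo_first_order(tt, noisy)
  expect_lt(abs(resn$k_prime - 0.05), 1.96 * resn$se + 1e-12)
  expect_error(pseudo_first_order(tt[1:3], conc[1:3]), ">= 4 points")
})

test_that("sliding windows track a constant decay rate", {
  tt <- 0:40
  conc <- 2e-5 * exp(-0.02 * tt)
  sl <- sliding_k_prime(tt, conc, width = 5)
  expect_true(all(abs(sl$k_prime - 0.02) < 1e-8))
})

test_that("non-enzymatic correction floors at zero and flags dominance", {
  expect_equal(correct_nonenzymatic(0.10, 0.02)$k, 0.08)
  r <- correct_nonenzymatic(0.02, 0.02)
  expect_equal(r$k, 0)
  r2 <- correct_nonenzymatic(0.05, 0.07)
  expect_equal(r2$k, 0)
  expect_true("negative_corrected" %in% r2$flags)
  expect_true("background_dominant" %in% correct_nonenzymatic(0.1, 0.06)$flags)
})

test_that("GSH dependence regression returns the second-order constant", {
  gsh <- c(2, 3, 4) * 1e-3
  k <- gsh_second_order(gsh, 10 * gsh)
  expect_equal(k$value, 10, tolerance = 1e-9)
  flat <- gsh_second_order(gsh, rep(0.02, 3))
  expect_true("gsh_independent" %in% flat$flags)
  # noisy line recovery within CI
  set.seed(5)
  kn <- gsh_second_order(rep(gsh, each = 4),
                         10 * rep(gsh, each = 4) + rnorm(12, 0, 1e-3))
  expect_lt(abs(kn$value - 10), 1.96 * kn$se + 1e-12)
  expect_error(gsh_second_order(c(2e-3, 2e-3, 2e-3), c(1, 2, 3)), "3 GSH")
})

test_that("Dalziel regression inverts the forward rate law exactly", {
  phi1 <- 1e-6; phi2 <- 5e-4; E <- 66.8e-9; R <- 20e-6
  gsh <- c(2, 3, 4) * 1e-3
  v0 <- E / (phi1 / R + phi2 / gsh)
  fit <- dalziel_fit(E, v0, R, gsh)
  expect_equal(fit$k_plus1, 1e6, tolerance = 1e-9)
  expect_equal(fit$k_plus2, 1 / phi2, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # grid over both substrates separates the coefficients equally well
  grid <- expand.grid(R = c(10, 20) * 1e-6, G = gsh)
  v0g <- E / (phi1 / grid$R + phi2 / grid$G)
  fitg <- dalziel_fit(E, v0g, grid$R, grid$G)
  expect_equal(fitg$phi1, phi1, tolerance = 1e-9)
  expect_equal(fitg$phi2, phi2, tolerance = 1e-9)
  # saturating-GSH limit: E/v0 loses its GSH dependence
  v0s <- E / (phi1 / R)
  fits <- dalziel_fit(E, rep(v0s, 3), R, gsh)
  expect_equal(fits$phi2, 0, tolerance = phi1 * 1e-6)
  expect_error(dalziel_fit(E, v0[1], R, gsh[1]), "rank-deficient")
})

test_that("E/v0 is exactly linear in 1/GSH under the forward model", {
  phi1 <- 1e-6; phi2 <- 5e-4; E <- 66.8e-9; R <- 20e-6
  gsh <- seq(1, 5) * 1e-3
  y <- E / (E / (phi1 / R + phi2 / gsh))
  fit <- lm(y ~ I(1 / gsh))
  r2 <- suppressWarnings(summary(fit)$r.squared)  # zero-residual fit
  expect_equal(r2, 1, tolerance = 1e-12)
})

test_that("full progression pipeline recovers the peroxidatic constant", {
  phi1 <- 1e-6; phi2 <- 5e-4; E <- 66.8e-9
  gshs <- c(2, 3, 4) * 1e-3
  pts <- do.call(rbind, lapply(gshs, function(g) {
    cv <- gen_progression_curve(phi1, phi2, E, gsh = g, duration = 180)
    tr <- substrate_trace(cv$time_s, cv$a340, rooh0 = attr(cv, "rooh0"))
    dalziel_points(tr$time_s, tr$conc, enzyme_conc = E, gsh_conc = g)
  }))
  fit <- dalziel_fit(pts$enzyme_conc, pts$v0, pts$rooh_conc, pts$gsh_conc)
  expect_lt(abs(fit$k_plus1 - 1e6) / 1e6, 0.05)
})

test_that("non-enzymatic channel is removed by the background correction", {
  # with enzyme and background channels both active, subtracting the
  # buffer-only pseudo-first-order constant recovers the enzymatic part
  phi1 <- 1e-6; phi2 <- 0; E <- 66.8e-9; g <- 3e-3; k_ne <- 5
  # phi2 = 0 limit: pure exponential decay at rate E/phi1 plus k_ne*gsh
  cv <- gen_progression_curve(phi1, phi2, E, gsh = g, k_ne = k_ne,
                              duration = 40)
  tr <- substrate_trace(cv$time_s, cv$a340, rooh0 = attr(cv, "rooh0"))
  k_tot <- pseudo_first_order(tr$time_s, tr$conc)$k_prime
  bg <- gen_progression_curve(phi1, phi2, 0, gsh = g, k_ne = k_ne,
                              duration = 40)
  trb <- substrate_trace(bg$time_s, bg$a340, rooh0 = attr(bg, "rooh0"))
  k_bg <- pseudo_first_order(trb$time_s, trb$conc)$k_prime
  expect_equal(k_bg, k_ne * g, tolerance = 1e-6)
  corrected <- correct_nonenzymatic(k_tot, k_bg)$k
  expect_equal(corrected, E / phi1, tolerance = 1e-4)
})

test_that("noisy progression replicates keep the constant inside the CI band", {
  phi1 <- 1e-6; phi2 <- 5e-4; E <- 66.8e-9
  gshs <- c(2, 3, 4) * 1e-3
  res <- vapply(1:25, function(i) {
    pts <- do.call(rbind, lapply(seq_along(gshs), function(j) {
      cv <- gen_progression_curve(phi1, phi2, E, gsh = gshs[j],
                                  duration = 180, noise_sd = 0.002,
                                  seed = 300 + 10 * i + j)
      tr <- substrate_trace(cv$time_s, cv$a340, rooh0 = attr(cv, "rooh0"),
                            noise_tol = 0.02)
      # wider windows average the 0.002 AU read noise down before the
      # reciprocal-rate regression; late low-substrate windows are dropped
      dalziel_points(tr$time_s, tr$conc, enzyme_conc = E, gsh_conc = gshs[j],
                     width = 20, min_fraction = 0.2)
    }))
    fit <- dalziel_fit(pts$enzyme_conc, pts$v0, pts$rooh_conc, pts$gsh_conc,
                       weights = pts$v0^2)
    c(err = (fit$k_plus1 - 1e6) / 1e6,
      z = (fit$phi1 - 1e-6) / fit$phi1_se)
  }, numeric(2))
  # 0.002 AU read noise on a ~0.12 AU signal: recovery is unbiased with
  # single-digit-percent spread, and the delta-method CI is near-nominal
  expect_lt(stats::median(abs(res["err", ])), 0.12)
  expect_gte(mean(abs(res["err", ]) < 0.25), 0.9)
  expect_gte(mean(abs(res["z", ]) < 1.96), 0.75)
})
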