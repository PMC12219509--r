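test_that("effective q corrects for aqueous-phase detergent", {
  # zero CBC leaves the nominal ratio untouched
  expect_equal(q_eff_fixed_cbc(28, 18, 0), 28 / 18)
  # DMPC:CHAPS working bicelle with the fixed CHAPS CBC
  expect_equal(q_eff_fixed_cbc(28, 18, default_cbc[["CHAPS"]]), 28 / 15.5,
               tolerance = 1e-12)
  expect_error(q_eff_fixed_cbc(28, 2.5, 2.5), "exceed")
  # strictly increasing as detergent decreases toward the CBC
  det <- seq(18, 3, by = -0.5)
  q <- vapply(det, function(d) q_eff_fixed_cbc(28, d, 2.5), numeric(1))
  expect_true(all(diff(q) > 0))
  expect_true(all(q >= 28 / 18))
})

test_that("ideal-mixing CBC is the mole-fraction harmonic mean of the CMCs", {
  expect_equal(cbc_ideal_mixing(0, cmc_lipid = 6e-6, cmc_detergent = 6), 6)
  expect_equal(cbc_ideal_mixing(1, cmc_lipid = 6e-6, cmc_detergent = 6), 6e-6)
  # equimolar DMPC:CHAPS from the reference CMCs
  expect_equal(cbc_ideal_mixing(0.5, 6e-6, 6), 1 / (0.5 / 6e-6 + 0.5 / 6),
               tolerance = 1e-15)
  # CBC always lies between the two CMCs for interior mole fractions
  for (chi in seq(0.05, 0.95, by = 0.09)) {
    v <- cbc_ideal_mixing(chi, 6e-6, 6)
    expect_true(v > 6e-6 && v < 6)
  }
  expect_error(cbc_ideal_mixing(0.5, 0, 6), "CMC")
})

test_that("Laurdan GP is the normalized 440/490 intensity contrast", {
  wl <- seq(400, 550, by = 1)
  flat <- rep(2, length(wl))
  expect_equal(as.numeric(gp_laurdan(wl, flat)), 0)
  # I490 = 0 gives +1
  spike <- ifelse(wl == 440, 5, 0)
  expect_equal(as.numeric(gp_laurdan(wl, spike)), 1)
  # I440 = 1, I490 = 3 gives -0.5
  spec <- ifelse(wl == 440, 1, ifelse(wl == 490, 3, 0.0))
  spec[wl == 490] <- 3; spec[wl == 440] <- 1
  expect_equal(as.numeric(gp_laurdan(wl, spec)), -0.5)
  # antisymmetry under swapping the two bands
  swapped <- spec; swapped[wl == 440] <- 3; swapped[wl == 490] <- 1
  expect_equal(as.numeric(gp_laurdan(wl, swapped)),
               -as.numeric(gp_laurdan(wl, spec)))
  # coarse grid falls back to interpolation
  wl2 <- seq(400, 550, by = 4)   # no sample within 1 nm of 490
  sp2 <- 1 + 0.01 * (wl2 - 400)
  g <- gp_laurdan(wl2, sp2)
  expect_equal(unname(attr(g, "lookup")["I490"]), "interpolated")
  i440 <- 1 + 0.01 * 40; i490 <- 1 + 0.01 * 90
  expect_equal(as.numeric(g), (i440 - i490) / (i440 + i490), tolerance = 1e-10)
  expect_error(gp_laurdan(wl, 0 * flat), "undefined")
  expect_error(gp_laurdan(seq(450, 550, 1), rep(1, 101)), "cover")
})

test_that("melting fit recovers sigmoid truth with flat and sloped baselines", {
  flat <- list(tm = 24, b = 1.5, m1 = 0, r1_0 = -0.2, m2 = 0, r2_0 = 0.32)
  sim <- sim_melting_curve(flat, n_points = 40, noise_sigma = 0, seed = 1)
  fit <- fit_melting(sim$temperature, sim$anisotropy)
  expect_equal(unname(fit$estimate["tm"]), 24, tolerance = 1e-6)
  expect_equal(unname(fit$estimate["b"]), 1.5, tolerance = 1e-5)

  sloped <- list(tm = 24, b = 1.5, m1 = -0.002, r1_0 = -0.2,
                 m2 = -0.001, r2_0 = 0.32)
  sim2 <- sim_melting_curve(sloped, n_points = 40, noise_sigma = 0, seed = 2)
  fit2 <- fit_melting(sim2$temperature, sim2$anisotropy)
  for (p in names(sloped)) {
    expect_equal(unname(fit2$estimate[c(tm = "tm", b = "b", m1 = "m1", r1_0 = "r1_0",
                                        m2 = "m2", r2_0 = "r2_0")[p]]),
                 sloped[[p]], tolerance = 1e-4)
  }
  # refit from the solution is a fixed point
  refit <- fit_melting(sim2$temperature, sim2$anisotropy,
                       init = as.list(fit2$estimate)[c("tm", "b", "m1", "r1_0",
                                                       "m2", "r2_0")])
  expect_equal(refit$estimate, fit2$estimate, tolerance = 1e-8)
})

test_that("melting Tm recovery is unbiased across the transition range at noise", {
  biases <- vapply(c(12, 20, 30), function(tm_true) {
    est <- vapply(1:20, function(s) {
      sim <- sim_melting_curve(list(tm = tm_true, b = 1.5, m1 = -0.002,
                                    r1_0 = -0.2, m2 = -0.001, r2_0 = 0.32),
                               n_points = 40, noise_sigma = 0.005, seed = s)
      unname(fit_melting(sim$temperature, sim$anisotropy)$estimate["tm"])
    }, numeric(1))
    mean(est) - tm_true
  }, numeric(1))
  expect_true(all(abs(biases) < 0.2))
})

test_that("SAXS peak position converts to bilayer thickness via L = 2*pi/Q", {
  expect_equal(thickness_from_peak(2 * pi / 40), 40)
  expect_equal(thickness_from_peak(0.157), 40.0, tolerance = 1e-2)
  expect_error(thickness_from_peak(0), "> 0")
})
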