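ctx37 <- thermo_context(310.15)
dc12pc <- three_state_params(-5.4, -26.4, 2.0, 7.2,
                             baselines = list(N = c(0, 0.01), I = c(0.5, -0.01),
                                              U = c(1, 0.005)))

test_that("equilibrium constants hit unity at the transition midpoints", {
  ks <- equilibrium_constants(dc12pc, 5.4 / 2.0, ctx37)
  expect_equal(ks$k_ni, 1, tolerance = 1e-12)
  ks2 <- equilibrium_constants(dc12pc, 26.4 / 7.2, ctx37)
  expect_equal(ks2$k_iu, 1, tolerance = 1e-12)
  # zero denaturant strongly favors the folded species
  k0 <- equilibrium_constants(dc12pc, 0, ctx37)
  expect_equal(k0$k_ni, exp(-5.4 / ctx37$rt), tolerance = 1e-12)
  expect_lt(k0$k_ni, 1e-3)
  # monotone increasing in denaturant
  d <- seq(0, 6, by = 0.25)
  kk <- equilibrium_constants(dc12pc, d, ctx37)
  expect_true(all(diff(kk$log_k_ni) > 0) && all(diff(kk$log_k_iu) > 0))
})

test_that("predicted observable interpolates the baselines through both transitions", {
  d <- seq(0, 6, by = 0.05)
  pr <- predict_observable(dc12pc, d, ctx37)
  # populations sum to one everywhere
  expect_true(all(abs(rowSums(pr$populations) - 1) < 1e-12))
  # folded limit at low denaturant, unfolded at high
  expect_equal(pr$populations$f_N[1], 1, tolerance = 1e-3)
  expect_equal(pr$populations$f_U[length(d)], 1, tolerance = 1e-2)
  # between the midpoints the native and intermediate trade places
  at_cm1 <- predict_observable(dc12pc, 2.7, ctx37)
  expect_equal(at_cm1$populations$f_N, at_cm1$populations$f_I, tolerance = 1e-6)
  expect_lt(at_cm1$populations$f_U, 1e-3)
  yn <- 0 + 0.01 * 2.7; yi <- 0.5 - 0.01 * 2.7
  expect_equal(at_cm1$signal, (yn + yi) / 2, tolerance = 1e-3)
})

test_that("evaluation is overflow-safe at extreme exponents", {
  # |exponent| ~ 500: dg and m chosen so m*D/RT reaches ~800 at D = 6
  extreme <- three_state_params(-100, -200, 50, 80)
  pr <- predict_observable(extreme, c(0, 3, 6), ctx37)
  expect_true(all(is.finite(pr$signal)))
  expect_true(all(abs(rowSums(pr$populations) - 1) < 1e-12))
})

test_that("zero-noise titrations return the generating landscape", {
  sim <- sim_denaturation_titration(dc12pc, n_points = 17, noise_sigma = 0,
                                    seed = 1)
  fit <- fit_three_state(sim$denaturant, sim$signal, fixed_m = c(2.0, 7.2),
                         context = ctx37)
  expect_equal(unname(fit$estimate["dg_ni"]), -5.4, tolerance = 1e-5)
  expect_equal(unname(fit$estimate["dg_iu"]), -26.4, tolerance = 1e-5)
  # floated m values (the thinner-bilayer workflow) also recover
  fitf <- fit_three_state(sim$denaturant, sim$signal, context = ctx37)
  expect_equal(unname(fitf$estimate["dg_ni"]), -5.4, tolerance = 1e-3)
  expect_equal(unname(fitf$estimate["m_iu"]), 7.2, tolerance = 1e-3)
  # refit from the solution is a fixed point
  refit <- fit_three_state(sim$denaturant, sim$signal, fixed_m = c(2.0, 7.2),
                           init = list(dg_ni = fit$estimate["dg_ni"],
                                       dg_iu = fit$estimate["dg_iu"]),
                           context = ctx37)
  expect_equal(refit$estimate, fit$estimate, tolerance = 1e-8)
})

test_that("noisy titrations keep the free energies within modest bias", {
  est <- vapply(1:30, function(s) {
    sim <- sim_denaturation_titration(dc12pc, n_points = 17, noise_sigma = 0.01,
                                      seed = s)
    fit <- fit_three_state(sim$denaturant, sim$signal, fixed_m = c(2.0, 7.2),
                           context = ctx37)
    fit$estimate[c("dg_ni", "dg_iu")]
  }, numeric(2))
  expect_lt(abs(mean(est[1, ]) + 5.4), 0.3)
  expect_lt(abs(mean(est[2, ]) + 26.4), 0.3)
})

test_that("degenerate titrations trigger diagnostics instead of silent fits", {
  # data only above both midpoints, with truth supplied as init
  d_high <- seq(4, 6, length.out = 10)
  y_high <- predict_observable(dc12pc, d_high, ctx37)$signal
  expect_error(fit_three_state(d_high, y_high, fixed_m = c(2.0, 7.2),
                               init = list(dg_ni = -5.4, dg_iu = -26.4),
                               context = ctx37),
               "no transition in range")
  # merged transitions: midpoint order inverted
  merged <- three_state_params(-20, -7, 4, 4)
  simm <- sim_denaturation_titration(merged, n_points = 17, noise_sigma = 0,
                                     seed = 2)
  expect_error(suppressWarnings(
    fit_three_state(simm$denaturant, simm$signal, fixed_m = c(4, 4),
                    context = ctx37)),
    "merged|unresolved|converge")
})

test_that("landscape summary reports levels relative to the unfolded state", {
  zero <- three_state_params(-1e-12, -1e-12, 1, 1)
  expect_true(all(abs(landscape_summary(zero)$levels) < 1e-10))
  ls <- landscape_summary(dc12pc)
  expect_equal(unname(ls$levels), c(0, -26.4, -31.8))
  expect_equal(ls$total, -31.8)
  expect_equal(unname(ls$midpoints), c(2.70, 26.4 / 7.2), tolerance = 1e-12)
  expect_equal(round(unname(ls$midpoints), 2), c(2.70, 3.67))
})
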