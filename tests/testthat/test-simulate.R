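test_that("generators are bit-reproducible under a fixed seed and spec", {
  t1 <- reference_second_truth()
  a <- sim_binding_titration("second", t1, noise_sigma = 0.01, seed = 42)
  b <- sim_binding_titration("second", t1, noise_sigma = 0.01, seed = 42)
  expect_identical(a$titration$signal, b$titration$signal)
  c3 <- sim_binding_titration("second", t1, noise_sigma = 0.01, seed = 43)
  expect_false(identical(a$titration$signal, c3$titration$signal))

  m <- list(tm = 24, b = 1.5, m1 = 0, r1_0 = -0.2, m2 = 0, r2_0 = 0.3)
  expect_identical(sim_melting_curve(m, seed = 7)$anisotropy,
                   sim_melting_curve(m, seed = 7)$anisotropy)

  ct1 <- sim_contact_traces(0.02, 0.025, n_molecules = 3, duration = 100,
                            frame_interval = 0.5, seed = 5)
  ct2 <- sim_contact_traces(0.02, 0.025, n_molecules = 3, duration = 100,
                            frame_interval = 0.5, seed = 5)
  expect_identical(lapply(ct1$traces, `[[`, "q"), lapply(ct2$traces, `[[`, "q"))

  p1 <- sim_mutant_panel(n_mutants = 12, seed = 9)
  p2 <- sim_mutant_panel(n_mutants = 12, seed = 9)
  expect_identical(p1$panel, p2$panel)
  # generators restore the session RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(sim_mutant_panel(n_mutants = 12, seed = 9))
  expect_identical(runif(1), before)
})

test_that("zero-noise outputs lie exactly on the forward model", {
  truth <- list(kd_biotin = 0.5, amplitude = 1, offset = 0.2, protein_total = 0.1)
  sim <- sim_binding_titration("first", truth, noise_sigma = 0, seed = 1)
  expect_equal(sim$titration$signal,
               eval_first_binding(sim$titration$msa_total, 0.5, 1, 0.2, 0.1))
  m <- list(tm = 20, b = 2, m1 = -0.001, r1_0 = -0.15, m2 = 0, r2_0 = 0.3)
  sm <- sim_melting_curve(m, noise_sigma = 0, seed = 1)
  expect_equal(sm$anisotropy,
               eval_melting(sm$temperature, 20, 2, -0.001, -0.15, 0, 0.3))
})

test_that("denaturation generator flags out-of-range midpoints", {
  inside <- three_state_params(-5.4, -26.4, 2.0, 7.2)
  expect_false(sim_denaturation_titration(inside, seed = 1)$spec$midpoint_warning)
  outside <- three_state_params(-1, -26.4, 2.0, 7.2)  # C_m(N-I) = 0.5 M < 1 M
  expect_true(sim_denaturation_titration(outside, seed = 1)$spec$midpoint_warning)
})

test_that("contact generator honors its kinetic contracts", {
  # k_on = 0: exactly one event per molecule (molecules start bound)
  sim0 <- sim_contact_traces(k_on = 0, k_off = 0.05, n_molecules = 10,
                             duration = 500, frame_interval = 0.5, seed = 3)
  nev <- vapply(sim0$traces, function(tr) nrow(detect_contact_events(tr)), 1L)
  expect_true(all(nev <= 1))
  expect_gt(sum(nev), 0)
  # aliasing warning when frames are coarser than the mean dwell
  expect_warning(sim_contact_traces(0.02, 0.5, n_molecules = 2, duration = 50,
                                    frame_interval = 3, seed = 1),
                 "alias")
  # Poisson counts keep bound frames in contact
  simp <- sim_contact_traces(0.02, 0.02, n_molecules = 5, duration = 200,
                             frame_interval = 0.5, seed = 4,
                             count_model = "poisson", count_mean = 3)
  qs <- unlist(lapply(simp$traces, `[[`, "q"))
  expect_true(all(qs[qs > 0] >= 1))
})

test_that("generator plus estimator closes on the truth (small scale)", {
  ctx <- thermo_context()
  truth <- reference_second_truth(ctx)
  # zero-noise closure through the fit
  sim <- sim_binding_titration("second", truth, noise_sigma = 0, seed = 10)
  fit <- fit_binding_model(sim$titration, "second",
                           fixed = list(kd_biotin = truth$kd_biotin), context = ctx)
  expect_equal(fit$dg_nd, -7.1, tolerance = 1e-6)
  # small seeded ensemble: empirical spread of estimates is comparable to
  # the asymptotic standard error the fit reports
  ests <- vapply(1:40, function(s) {
    simn <- sim_binding_titration("second", truth, noise_sigma = 0.01, seed = s)
    f <- fit_binding_model(simn$titration, "second",
                           fixed = list(kd_biotin = truth$kd_biotin), context = ctx)
    c(f$dg_nd, f$dg_se)
  }, numeric(2))
  ratio <- sd(ests[1, ]) / mean(ests[2, ])
  expect_gt(ratio, 0.7); expect_lt(ratio, 1.3)
})

test_that("mutant-panel generator supports exact null and prescribed slopes", {
  exact <- sim_mutant_panel(n_mutants = 12, true_slope = 1, noise_sigma = 0,
                            seed = 2)
  r <- slope_regression(exact$panel$ddg_C, exact$panel$ddg_N)
  expect_equal(r$slope, 1, tolerance = 1e-12)
  expect_equal(r$sse, 0, tolerance = 1e-20)
  # zero-noise panels make Chow's test degenerate, which is flagged
  g1 <- exact$panel[1:6, ]; g2 <- exact$panel[7:12, ]
  expect_true(chow_test(g1$ddg_C, g1$ddg_N, g2$ddg_C, g2$ddg_N)$degenerate)
  sloped <- sim_mutant_panel(n_mutants = 200, true_slope = 1.7,
                             noise_sigma = 0.3, seed = 3)
  r2 <- slope_regression(sloped$panel$ddg_C, sloped$panel$ddg_N)
  expect_equal(r2$slope, 1.7, tolerance = 0.1)
  # burial composition follows the requested mix
  expect_true(all(levels(burial_class(sloped$panel$f_asa)) %in%
                  c("buried", "partially_buried", "exposed")))
})
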