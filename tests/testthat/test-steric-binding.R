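test_that("first-binding quadratic matches limits and the mass-balance oracle", {
  # stoichiometric limit: Kd = 0 and [mSA] = P_T/2 binds half the protein
  expect_equal(eval_first_binding(0.05, 0, 1, 0, protein_total = 0.1), 0.5)
  # zero ligand returns the offset
  expect_equal(eval_first_binding(0, 0.5, 1, 0.2, protein_total = 0.1), 0.2)
  # spec's single point against the brute-force equilibrium solver
  frac <- oracle_single_site_fraction(1, kd = 1, protein_total = 0.1)
  expect_equal(eval_first_binding(1, 1, 1, 0, protein_total = 0.1), frac,
               tolerance = 1e-10)
  # property: equality with the oracle over random (P_T, Kd, [mSA]) draws
  set.seed(42)
  for (i in 1:50) {
    pt <- runif(1, 0.01, 10); kd <- runif(1, 0, 5); lt <- runif(1, 0, 30)
    expect_equal(eval_first_binding(lt, kd, 1, 0, pt),
                 oracle_single_site_fraction(lt, kd, pt),
                 tolerance = 1e-10)
  }
  # output bounded between offset and offset + amplitude
  v <- eval_first_binding(seq(0, 60, by = 1), 0.5, 2, 1, protein_total = 1)
  expect_true(all(v >= 1 - 1e-12 & v <= 3 + 1e-12))
  expect_error(eval_first_binding(1, -0.1, 1, 0, 1), "kd_biotin")
})

test_that("competition closed form has the printed limits and documented oracle deviation", {
  # zero competitor: the root vanishes, leaving the offset
  expect_equal(eval_competition(0, 0.5, 1, 0.3, protein_total = 1, labeled_total = 2),
               0.3)
  # symmetric case k_ratio = 1, C_T = P_T reduces to a one-ligand-like root
  p <- 1; m <- 3
  simplified <- (-(p + m) + sqrt((p + m)^2 + 4 * p * m)) / (2 * p)
  expect_equal(eval_competition(m, 1, 1, 0, p, p), simplified, tolerance = 1e-12)
  # monotone increasing in competitor at fixed parameters
  v <- eval_competition(seq(0, 50, length.out = 40), 0.5, 1, 0, 1, 2)
  expect_true(all(diff(v) > 0))
  # P_T = 0 divides by zero
  expect_error(eval_competition(1, 0.5, 1, 0, protein_total = 0, labeled_total = 2),
               "protein_total")
  # systematic deviation of the printed form from the exact coupled
  # equilibrium (tight-binding limit): measured once and recorded here.
  cf <- eval_competition(5, 0.5, 1, 0, protein_total = 1, labeled_total = 2)
  exact <- solve_competition_equilibrium(5, kd_label = 1e-4, k_ratio = 0.5,
                                         protein_total = 1, labeled_total = 2)
  expect_equal(cf, 0.7284161, tolerance = 1e-6)
  expect_equal(exact$frac_unlabeled, 0.8211, tolerance = 1e-3)
  expect_equal(abs(cf - exact$frac_unlabeled), 0.0927, tolerance = 2e-3)
})

test_that("second-binding isotherm honors plateaus, half-point, and monotonicity", {
  # half-saturation by construction: K_D = 1, Kd = 1 uM at [mSA] = 2 uM
  expect_equal(eval_second_binding(2, 1, 1, f0 = 1, f_inf = 0), 0.5)
  # zero mSA evaluates the F_o limit instead of dividing by zero
  expect_equal(eval_second_binding(0, 1e-4, 0.5, f0 = 1, f_inf = 0.1), 1)
  # fully denatured limit: half-point collapses to the raw biotin affinity
  big_kd <- 1e9
  expect_equal(eval_second_binding(0.5, big_kd, 0.5, 1, 0), 0.5, tolerance = 1e-8)
  # half-point from the stated bicelle stability at bench temperature
  ctx <- thermo_context(297.65)
  kd_denat <- exp(-7.1 / ctx$rt)
  half <- 2e-5 * (1 + 1 / kd_denat)
  expect_equal(eval_second_binding(half, kd_denat, 2e-5, 1, 0), 0.5,
               tolerance = 1e-12)
  # monotone with plateaus bracketing all values (F_inf < F_o)
  msa <- c(0, exp(seq(log(0.01), log(60), length.out = 30)))
  v <- eval_second_binding(msa, 1e-4, 2e-5, 1, 0.1)
  expect_true(all(diff(v) <= 0))
  expect_true(all(v <= 1 & v >= 0.1))
  expect_error(eval_second_binding(1, 0, 0.5, 1, 0), "k_denat")
})

test_that("stability-difference arithmetic propagates errors in quadrature", {
  wt <- stability_record("N", "WT", "bicelle", -7.1, 0.2)
  mut <- stability_record("N", "A123V", "bicelle", -5.0, 0.2)
  d <- ddg_wt_minus_mut(wt, mut)
  expect_equal(d$ddg, -2.1)
  expect_equal(d$se, sqrt(0.08), tolerance = 1e-12)
  # identical records: zero with sqrt(2) * SE
  d0 <- ddg_wt_minus_mut(wt, stability_record("N", "WT", "bicelle", -7.1, 0.2))
  expect_equal(d0$ddg, 0)
  expect_equal(d0$se, sqrt(2) * 0.2)
  # contract: mismatched environment or construct errors out
  expect_error(ddg_wt_minus_mut(wt, stability_record("N", "A123V", "micelle", -5, 0.2)),
               "environment")
  expect_error(ddg_wt_minus_mut(wt, stability_record("C", "A123V", "bicelle", -5, 0.2)),
               "construct")
  # environment comparison at fixed construct/mutation
  mic <- stability_record("N", "WT", "micelle", -5.8, 0.2)
  env <- ddg_environment(wt, mic)
  expect_equal(env$ddg, -1.3, tolerance = 1e-12)
  expect_error(ddg_environment(wt, stability_record("C", "WT", "micelle", -4.7, 0.1)),
               "construct")
})
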