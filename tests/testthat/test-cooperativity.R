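test_that("dddg arithmetic and quadrature are exact", {
  expect_equal(compute_dddg(1.2, 1.2)$dddg, 0)
  expect_equal(compute_dddg(2.0, 0.5)$dddg, 1.5)
  expect_equal(compute_dddg(2.0, 0.5, 0.2, 0.2)$se, sqrt(0.08), tolerance = 1e-12)
  expect_error(compute_dddg(NA, 0.5), "both subdomain")
})

test_that("classification respects the printed interval boundaries", {
  ctx <- thermo_context()
  rt <- ctx$rt
  lab <- function(x, ...) as.character(classify_cooperativity(x, ctx, ...))
  expect_equal(lab(0), "cooperative")
  # boundaries: +/-RT inclusive to cooperative, +/-2RT inclusive to moderate
  expect_equal(lab(rt), "cooperative")
  expect_equal(lab(-rt), "cooperative")
  expect_equal(lab(rt + 1e-9), "moderately_localized_N")
  expect_equal(lab(-rt - 1e-9), "moderately_localized_C")
  expect_equal(lab(2 * rt), "moderately_localized_N")
  expect_equal(lab(-2 * rt), "moderately_localized_C")
  expect_equal(lab(2 * rt + 1e-9), "localized_N")
  expect_equal(lab(-2 * rt - 1e-9), "localized_C")
  # rule application at the rounded cutoff: 1.5 kcal/mol with RT = 0.6
  expect_equal(lab(1.5, rt_cutoff = 0.6), "localized_N")
  # narrow scheme halves the thresholds
  expect_equal(lab(0.75 * rt, scheme = "narrow"), "moderately_localized_N")
  expect_equal(lab(rt, scheme = "narrow"), "moderately_localized_N")
  expect_equal(lab(rt + 1e-9, scheme = "narrow"), "localized_N")
  expect_error(classify_cooperativity(NaN), "finite")
})

test_that("classification partitions the line and is stable off-boundary", {
  ctx <- thermo_context()
  set.seed(7)
  x <- c(runif(400, -3, 3), rnorm(100, 0, 0.8))
  labs <- classify_cooperativity(x, ctx)
  expect_false(any(is.na(labs)))          # every value gets exactly one label
  # off-boundary values keep their label under tiny perturbation
  off <- x[pmin(abs(abs(x) - ctx$rt), abs(abs(x) - 2 * ctx$rt)) > 1e-6]
  expect_equal(classify_cooperativity(off + 1e-12, ctx),
               classify_cooperativity(off - 1e-12, ctx))
  # a panel entirely within |dddg| <= RT is called 100% cooperative
  panel <- data.frame(mutation = sprintf("M%d", 1:20),
                      ddg_N = seq(0, 0.5, length.out = 20),
                      ddg_C = seq(0, 0.5, length.out = 20) -
                        seq(-0.5, 0.5, length.out = 20) * 0)
  panel$ddg_C <- panel$ddg_N - runif(20, -ctx$rt, ctx$rt)
  calls <- cooperativity_calls(panel, ctx)
  expect_true(all(calls$label == "cooperative"))
})

test_that("burial classes follow the f_ASA cutpoints", {
  expect_equal(as.character(burial_class(0)), "buried")
  expect_equal(as.character(burial_class(0.1)), "partially_buried")
  expect_equal(as.character(burial_class(0.5)), "exposed")
  expect_equal(as.character(burial_class(1e-6)), "partially_buried")
  expect_true(is.na(burial_class(NA)))
  expect_error(burial_class(1.2), "0, 1")
  expect_error(burial_class(-0.1), "0, 1")
})

test_that("slope regression matches the closed-form normal equations", {
  r <- slope_regression(c(0, 1, 2), c(1, 3, 5))
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 1)
  r2 <- slope_regression(1:5, 1:5)
  expect_equal(r2$slope, 1); expect_equal(r2$pearson_r, 1); expect_equal(r2$sse, 0)
  set.seed(11)
  x <- rnorm(20); y <- 1.7 * x + rnorm(20, 0, 0.3)
  r3 <- slope_regression(x, y)
  sxx <- sum((x - mean(x))^2); sxy <- sum((x - mean(x)) * (y - mean(y)))
  expect_equal(r3$slope, sxy / sxx, tolerance = 1e-12)
  expect_equal(r3$intercept, mean(y) - (sxy / sxx) * mean(x), tolerance = 1e-12)
  expect_error(slope_regression(rep(2, 5), 1:5), "zero variance")
  expect_error(slope_regression(1:2, 1:2), "at least 3")
})

test_that("Chow's test reproduces the printed formula and its contracts", {
  # hand-sized dataset evaluated directly from the formula
  x1 <- c(0, 1, 2, 3); y1 <- c(0.1, 1.2, 1.9, 3.1)
  x2 <- c(0, 1, 2, 3); y2 <- c(-0.2, 1.6, 3.1, 4.9)
  res <- chow_test(x1, y1, x2, y2)
  expect_equal(res$chow_F, oracle_chow_f(x1, y1, x2, y2), tolerance = 1e-12)
  expect_equal(unname(res$dof["df2"]), 4)
  expect_equal(res$chow_p, stats::pf(res$chow_F, 2, 4, lower.tail = FALSE))
  # symmetric under swapping groups
  swapped <- chow_test(x2, y2, x1, y1)
  expect_equal(swapped$chow_F, res$chow_F)
  # invariant to a common affine rescaling of x
  scaled <- chow_test(2 * x1 + 3, y1, 2 * x2 + 3, y2)
  expect_equal(scaled$chow_F, res$chow_F, tolerance = 1e-10)
  # same-line groups: small F, large p
  set.seed(3)
  xa <- runif(12, 0, 3); xb <- runif(12, 0, 3)
  null_res <- chow_test(xa, xa + rnorm(12, 0, 0.2), xb, xb + rnorm(12, 0, 0.2))
  expect_gt(null_res$chow_p, 0.05)
  # perfectly collinear groups flag degenerate rather than fabricate F
  deg <- chow_test(0:3, 0:3, 0:3, (0:3) * 2)
  expect_true(deg$degenerate)
  expect_true(is.na(deg$chow_F))
})
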