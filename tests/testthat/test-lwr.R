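test_that("fit_lwr recovers exact power-law parameters to numerical precision", {
  for (pars in list(c(0.01, 3), c(0.0061, 3.33), c(0.05, 2.7))) {
    f <- fit_lwr(power_law_sample(pars[1], pars[2]))
    expect_lt(abs(f$a - pars[1]) / pars[1], 1e-9)
    expect_lt(abs(f$b - pars[2]) / pars[2], 1e-9)
    expect_equal(f$r2, 1)
  }
  expect_equal(fit_lwr(power_law_sample(0.01, 3))$pattern, "isometric")
  expect_equal(fit_lwr(power_law_sample(0.0061, 3.33))$pattern,
               "positive_allometric")
})

test_that("rescaling weights shifts a proportionally and leaves b and r2 alone", {
  set.seed(10)
  smp <- simulate_sample(jamuna_config(n_fish = 200, seed = 10))
  f1 <- fit_lwr(smp)
  smp2 <- biometric_sample(smp$total_length, smp$body_weight * 2.5)
  f2 <- fit_lwr(smp2)
  expect_equal(f2$a, 2.5 * f1$a, tolerance = 1e-10)
  expect_equal(f2$b, f1$b, tolerance = 1e-12)
  expect_equal(f2$r2, f1$r2, tolerance = 1e-12)
})

test_that("the b confidence interval attains near-nominal coverage under the generating model", {
  covered <- vapply(1:100, function(s) {
    f <- fit_lwr(simulate_sample(jamuna_config(seed = s)))
    f$b_ci95[1] <= 3.33 && 3.33 <= f$b_ci95[2]
  }, logical(1))
  expect_gte(sum(covered), 93)
})

test_that("isometry testing classifies slopes against their reference", {
  none <- test_isometry(list(b = 3, se_b = 0.05, n = 100), reference = 3)
  expect_equal(none$statistic, 0)
  expect_equal(none$p_value, 1)
  expect_equal(none$verdict, "isometric")

  # field-scale LWR: b = 3.33, se from a CI half-width of 0.06
  strong <- test_isometry(list(b = 3.33, se_b = 0.0306, n = 725),
                          reference = 3)
  expect_lt(strong$p_value, 1e-4)
  expect_equal(strong$verdict, "positive_allometric")

  below <- test_isometry(list(b = 2.6, se_b = 0.05, n = 100), reference = 3)
  expect_equal(below$verdict, "negative_allometric")
  # symmetry: reflecting b about the reference flips the label only
  expect_equal(test_isometry(list(b = 3.4, se_b = 0.05, n = 100), 3)$p_value,
               test_isometry(list(b = 2.6, se_b = 0.05, n = 100), 3)$p_value)

  expect_error(test_isometry(list(b = 3, se_b = 0, n = 10)), "degenerate")
})

test_that("fit_llr reproduces a noise-free linear TL-SL relation and flags positive allometry", {
  sl <- seq(2, 7, by = 0.5)
  smp <- biometric_sample(total_length = 0.1284 + 1.20 * sl,
                          standard_length = sl,
                          body_weight = 0.006 * sl^3)
  f <- fit_llr(smp)
  expect_equal(f$intercept, 0.1284, tolerance = 1e-9)
  expect_equal(f$slope, 1.20, tolerance = 1e-9)
  expect_equal(f$r2, 1)
  expect_equal(f$pattern, "positive_allometric")

  ident <- biometric_sample(total_length = sl, standard_length = sl,
                            body_weight = 0.006 * sl^3)
  fi <- fit_llr(ident)
  expect_equal(fi$slope, 1, tolerance = 1e-12)
  expect_equal(fi$intercept, 0, tolerance = 1e-9)
  expect_equal(fi$pattern, "isometric")

  # generating slope is ~1 / mean(SL/TL), up to mild attenuation from the
  # ratio noise entering the regressor
  smp <- simulate_sample(jamuna_config(seed = 1))
  f <- fit_llr(smp)
  expect_lt(abs(f$slope - 1 / 0.813) * 0.813, 0.02)

  no_sl <- biometric_sample(total_length = sl, body_weight = 0.006 * sl^3)
  expect_error(fit_llr(no_sl), "standard length missing")
})

test_that("ANCOVA separates slope and intercept differences between groups", {
  smp <- simulate_sample(jamuna_config(n_fish = 100, seed = 4))
  same <- compare_groups(list(a = smp, b = smp))
  expect_equal(same$p_slope_equality, 1)

  g1 <- simulate_sample(jamuna_config(n_fish = 300, lwr_b = 3.0,
                                      weight_sigma = 0.1, seed = 21))
  g2 <- simulate_sample(jamuna_config(n_fish = 300, lwr_b = 3.5,
                                      weight_sigma = 0.1, seed = 22))
  diff_slope <- compare_groups(list(g1 = g1, g2 = g2))
  expect_lt(diff_slope$p_slope_equality, 0.01)
  expect_true(is.na(diff_slope$p_intercept_equality))

  g3 <- simulate_sample(jamuna_config(n_fish = 300, weight_sigma = 0.1,
                                      seed = 23))
  g4 <- simulate_sample(jamuna_config(n_fish = 300, weight_sigma = 0.1,
                                      lwr_a = 0.0061 * exp(0.5), seed = 24))
  diff_int <- compare_groups(list(g3 = g3, g4 = g4))
  expect_gte(diff_int$p_slope_equality, 0.01)
  expect_lt(diff_int$p_intercept_equality, 0.01)
})

test_that("the form factor rescales the intercept to b = 3 and orders by a", {
  expect_equal(form_factor(0.01, 3)$a3_0, 0.01)
  expect_lt(abs(form_factor(0.0061, 3.33)$a3_0 - 0.0172), 2e-4)
  expect_equal(round(form_factor(0.0060, 3.06)$a3_0, 3), 0.007)
  # classification against the short-and-deep band
  expect_equal(form_factor(0.018, 3)$body_shape, "short and deep")
  expect_equal(form_factor(0.01, 3)$body_shape, "elongated")
  expect_equal(form_factor(0.025, 3)$body_shape,
               "rounder than short-and-deep")
  # strictly increasing in a, at fixed b
  as <- seq(0.002, 0.02, by = 0.002)
  vals <- vapply(as, function(a) form_factor(a, 3.2)$a3_0, numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_error(form_factor(-1, 3), "a must be > 0")
})
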