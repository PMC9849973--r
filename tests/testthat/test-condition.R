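test_that("condition indices satisfy their defining identities per fish", {
  smp <- biometric_sample(total_length = c(10, 5, 6.5),
                          body_weight = c(1, 0.9, 2.2))
  fit <- list(a = 0.0061, b = 3.33)
  prof <- condition_profile(smp, fit)
  expect_equal(prof$kf[1], 0.1)           # 100 * 1 / 10^3
  expect_equal(prof$wr, 100 * prof$kr)
  expect_equal(prof$ka, 0.0061 * prof$kr)
  expect_equal(prof$ws, 0.0061 * smp$total_length^3.33)
  # order invariance
  smp_rev <- biometric_sample(rev(smp$total_length), rev(smp$body_weight))
  expect_equal(condition_profile(smp_rev, fit)$kr, rev(prof$kr))
})

test_that("weights lying exactly on the curve give KR = 1 and WR = 100", {
  smp <- power_law_sample(0.0061, 3.33)
  prof <- condition_profile(smp, list(a = 0.0061, b = 3.33))
  expect_equal(prof$kr, rep(1, nrow(smp)))
  expect_equal(prof$wr, rep(100, nrow(smp)))
})

test_that("mean relative weight and relative condition are centred on the fitting sample", {
  smp <- simulate_sample(jamuna_config(seed = 1))
  fit <- fit_lwr(smp)
  prof <- condition_profile(smp, fit)
  expect_gt(mean(prof$wr), 95)
  expect_lt(mean(prof$wr), 110)
  expect_lt(abs(mean(prof$kr) - 1), 0.1)
})

test_that("Spearman associations vs length behave for monotone, tied-scale and drifting indices", {
  smp <- power_law_sample(0.0061, 3.33)
  prof <- condition_profile(smp, list(a = 0.0061, b = 3.33))
  assoc <- associations_vs_length(prof)
  # KF = 100 a L^(b-3) is strictly increasing in L when b > 3
  expect_equal(assoc$rs[assoc$index == "kf"], 1)
  # KR and WR are constant here: flagged, not correlated
  expect_match(assoc$flag[assoc$index == "kr"], "undefined")
  expect_match(assoc$flag[assoc$index == "wr"], "undefined")

  smp <- simulate_sample(jamuna_config(seed = 1))
  prof <- condition_profile(smp, fit_lwr(smp))
  assoc <- associations_vs_length(prof)
  # WR = 100 KR is rank-preserving, so the two associations coincide exactly
  expect_identical(assoc$rs[assoc$index == "wr"],
                   assoc$rs[assoc$index == "kr"])
  expect_identical(assoc$rs[assoc$index == "ka"],
                   assoc$rs[assoc$index == "kr"])
  # generating b > 3 makes Fulton's condition drift upward with length
  expect_gt(assoc$rs[assoc$index == "kf"], 0)
  expect_lt(assoc$p_value[assoc$index == "kf"], 0.01)
  expect_true(all(assoc$rs_ci_low <= assoc$rs & assoc$rs <= assoc$rs_ci_high))
})

test_that("the relative-weight balance test calibrates against exact signed-rank enumeration", {
  # symmetric around 100: exact enumeration gives p deep in the null
  expect_gt(balance_test(c(98, 102, 97, 103, 96, 104))$p_value, 0.5)
  # all above 100, n = 10: the smallest attainable two-sided exact p
  expect_equal(balance_test(100 + 1:10)$p_value, 2 / 2^10)
  expect_equal(balance_test(100 + 1:10)$verdict, "imbalanced habitat")
  # degenerate: every fish exactly at the reference
  z <- balance_test(rep(100, 10))
  expect_match(z$flag, "zero differences")
  expect_error(balance_test(c(101, 99)), "n >= 6")
})

test_that("heavy weight skew is detected as an imbalanced habitat at field sample size", {
  p <- vapply(1:20, function(s) {
    smp <- simulate_sample(jamuna_config(weight_sigma = 0.35, seed = s))
    balance_test(condition_profile(smp, fit_lwr(smp)))$p_value
  }, numeric(1))
  expect_lt(median(p), 0.05)
})
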