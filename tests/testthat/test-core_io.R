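test_that("CSV round trip is the identity on records, in file order", {
  smp <- tiny_sample()
  path <- withr::local_tempfile(fileext = ".csv")
  write_biometric_table(smp, path)
  back <- read_biometric_table(path, label = "tiny")
  expect_equal(back$total_length, smp$total_length)
  expect_equal(back$standard_length, smp$standard_length)
  expect_equal(back$body_weight, smp$body_weight)
  # and again through a second cycle, to full stored precision
  smp2 <- biometric_sample(total_length = pi * 1:3,
                           body_weight = exp(1:3) / 10)
  write_biometric_table(smp2, path)
  expect_equal(read_biometric_table(path)$total_length, pi * 1:3)
})

test_that("reading rejects malformed and invalid tables with row context", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("tl_cm,sl_cm,bw_g", "3.0,2.4,0.25", "5.0,4.1,0", "7,5.7,3.4"),
             path)
  expect_error(read_biometric_table(path), "row 2")
  writeLines(c("tl_cm,bw_g", "3.0,0.25"), path)
  expect_error(read_biometric_table(path), "sl_cm")
  expect_s3_class(
    read_biometric_table(path, column_map = c(total_length = "tl_cm",
                                              body_weight = "bw_g")),
    "biometric_sample")
  writeLines(c("tl_cm,sl_cm,bw_g", "3.0,2.4,heavy"), path)
  expect_error(
    read_biometric_table(path), "non-numeric body_weight on row 1")
})

test_that("sample construction enforces the biometric invariants", {
  expect_error(biometric_sample(numeric(0), numeric(0)), "empty")
  expect_error(biometric_sample(c(3, -1), c(1, 1)), "total length")
  expect_error(biometric_sample(c(3, 4), c(1, 0)), "body weight")
  expect_error(biometric_sample(c(3, 4), c(1, 1),
                                standard_length = c(2.5, 4.5)),
               "standard length")
})

test_that("descriptive statistics match hand values and are permutation invariant", {
  d <- descriptive_stats(c(1, 2, 3))
  expect_equal(d$mean, 2)
  expect_equal(d$sd, 1)
  expect_equal(d$minimum, 1)
  expect_equal(d$maximum, 3)
  # Student-t CI: 2 +/- qt(.975, 2) * 1/sqrt(3)
  expect_equal(d$ci95_high - d$mean, qt(0.975, 2) / sqrt(3))

  const <- descriptive_stats(rep(5, 4))
  expect_equal(const$sd, 0)
  expect_equal(const$ci95_low, 5)
  expect_equal(const$ci95_high, 5)

  set.seed(7)
  v <- rlnorm(50)
  expect_equal(descriptive_stats(v), descriptive_stats(rev(sample(v))))
  expect_error(descriptive_stats(numeric(0)), "empty")
})

test_that("the sample mean estimator is unbiased at field-sample scale", {
  # Monte-Carlo oracle: draws around the field sample's TL moments
  set.seed(42)
  v <- rnorm(1000, mean = 5.84, sd = 1.14)
  se <- 1.14 / sqrt(1000)
  expect_lt(abs(descriptive_stats(v)$mean - 5.84), 3 * se)
})

test_that("length binning uses left-closed right-open classes and conserves mass", {
  lfd <- bin_lengths(c(2.7, 2.74))
  expect_equal(nrow(lfd), 1L)
  expect_equal(lfd$lower, 2.5)
  expect_equal(lfd$upper, 3.0)
  expect_equal(lfd$count, 2L)

  lfd <- bin_lengths(c(5.5, 5.7, 5.99, 6.0))
  expect_equal(lfd$count[lfd$lower == 5.5], 3L)
  expect_equal(lfd$count[lfd$lower == 6.0], 1L)

  set.seed(3)
  lengths <- runif(400, 2, 9)
  for (w in c(0.25, 0.5, 1)) {
    for (anchor in c(0, 0.1, 1.9)) {
      expect_equal(sum(bin_lengths(lengths, width = w, anchor = anchor)$count),
                   400L)
    }
  }
  # ties resolve to the lowest bin index
  tie <- bin_lengths(c(1.1, 1.1, 2.1, 2.1, 3.1))
  expect_equal(attr(tie, "modal_bin"), 1L)
  expect_error(bin_lengths(c(1, 2), anchor = 1.5), "anchor")
})

test_that("the default simulated catch has its modal class at 5.5-6.0 cm", {
  lfd <- bin_lengths(simulate_sample(jamuna_config(seed = 1)))
  mb <- attr(lfd, "modal_bin")
  expect_equal(lfd$lower[mb], 5.5)
  expect_equal(lfd$upper[mb], 6.0)
})

test_that("normality screening behaves across clean, bimodal and degenerate input", {
  p_ok <- vapply(1:100, function(s) {
    set.seed(s)
    normality_test(rnorm(500))$p.value
  }, numeric(1))
  expect_gte(sum(p_ok > 0.01), 95)

  set.seed(1)
  bimodal <- c(rnorm(250, -3, 0.5), rnorm(250, 3, 0.5))
  expect_lt(normality_test(bimodal)$p.value, 1e-4)

  expect_error(normality_test(rep(1.5, 20)), "insufficient variation")
  expect_error(normality_test(c(1, 2)), "n >= 3")
})
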