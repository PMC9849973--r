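test_that("empirical asymptotic length matches published cross-population values", {
  expect_equal(estimate_linf(8.5), 9.09, tolerance = 0.001)
  expect_equal(estimate_linf(13.4), 14.23, tolerance = 0.001)
  expect_equal(estimate_linf(1.0), 10^0.044)
  # strictly increasing and above lmax over the plausible size range
  grid <- seq(1, 100, by = 0.5)
  vals <- estimate_linf(grid)
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals > grid))
})

test_that("asymptotic weight follows the length-weight relationship at the asymptote", {
  linf <- estimate_linf(8.5)
  expect_equal(estimate_winf(0.0061, 3.33, linf), 9.49, tolerance = 0.01)
  expect_equal(estimate_winf(1, 1, 5), 5)
  expect_equal(estimate_winf(0.0060, 3.06, 7.83), 0.0060 * 7.83^3.06)
})

test_that("growth performance index matches its value and compensation property", {
  expect_equal(phi_prime(0.94, estimate_linf(8.5)), 1.89, tolerance = 0.005)
  expect_equal(phi_prime(1, 10), 2)
  expect_equal(phi_prime(0.5, 20), log10(0.5) + 2 * log10(20))
  # trading K for Linf^2 leaves the index unchanged
  for (c_ in c(0.5, 2, 3.7)) {
    expect_equal(phi_prime(0.94 * c_^2, 9.09 / c_), phi_prime(0.94, 9.09),
                 tolerance = 1e-12)
  }
})

test_that("longevity and growth coefficient are exact inverses", {
  expect_equal(lifespan_from_k(0.94), 3 / 0.94)
  expect_equal(round(lifespan_from_k(0.94), 1), 3.2)
  expect_equal(lifespan_from_k(3), 1)
  for (k in c(0.1, 0.94, 2.5)) {
    expect_equal(k_from_lifespan(lifespan_from_k(k)), k, tolerance = 1e-15)
  }
})

test_that("age at zero length is negative and matches direct evaluation", {
  # frozen direct evaluation of the empirical equation at the study inputs
  expect_equal(estimate_t0(9.09, 0.94), -0.23544, tolerance = 1e-4)
  expect_equal(estimate_t0(10, 1), -10^(-0.3922 - 0.2752))
  for (linf in c(5, 9.09, 50)) {
    for (k in c(0.2, 0.94, 2)) expect_lt(estimate_t0(linf, k), 0)
  }
})

test_that("K from maturity parameters supports both equation readings", {
  expect_equal(k_from_maturity(5.4, 9.09, 0.90), log(1 + 5.4 / 9.09) / 0.90)
  expect_equal(k_from_maturity(5.4, 9.09, 0.90), 0.518, tolerance = 1e-3)
  expect_equal(k_from_maturity(5.4, 9.09, 0.90, product = TRUE),
               log(1 + 5.4 / 9.09) * 0.90)
  expect_lt(k_from_maturity(1e-8, 9.09, 0.90), 1e-8)  # lm -> 0 limit
  expect_error(k_from_maturity(10, 9.09, 0.90), "domain")
})

test_that("the growth curve is anchored, concave, bounded, and inverts exactly", {
  expect_equal(vbgf_length_at_age(9.09, 0.94, t0 = -0.2, t = -0.2), 0)
  expect_equal(vbgf_length_at_age(9.09, 0.94, 0, 3.2), 8.641,
               tolerance = 1e-3)
  ts <- seq(0, 6, by = 0.05)
  lt <- vbgf_length_at_age(9.09, 0.94, 0, ts)
  expect_true(all(diff(lt) > 0))
  expect_true(all(diff(diff(lt)) < 0))
  expect_true(all(lt < 9.09))
  # inverse identity both ways
  expect_equal(relative_age_of_length(
    vbgf_length_at_age(9.09, 0.94, 0, ts), 9.09, 0.94), ts,
    tolerance = 1e-12)
  expect_error(vbgf_length_at_age(9.09, 0.94, 0, -1), "t must be")
})

test_that("growth_parameters assembles a consistent parameter set", {
  g <- growth_parameters(lmax = 8.5, k = 0.94, a = 0.0061, b = 3.33)
  expect_equal(g$tmax, 3 / g$k)
  expect_equal(g$winf, 0.0061 * g$linf^3.33)
  expect_equal(g$phi_prime, log10(g$k) + 2 * log10(g$linf))
  expect_lt(g$t0, 0)
  expect_equal(g$k_source, "input")
})
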