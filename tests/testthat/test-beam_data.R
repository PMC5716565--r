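# beam_data: PDD queries, profile metrics, output-factor daisy-chaining.

test_that("PDD interpolation and range checks", {
  p <- scan_profile(c(0, 15, 90, 110), c(80, 100, 68, 64), axis = "depth")
  expect_equal(pdd_at_depth(p, 15), 100)
  expect_equal(pdd_at_depth(p, 100), 66)
  expect_error(pdd_at_depth(p, -5), class = "linacqa_range_error")
  expect_error(pdd_at_depth(p, 200), class = "linacqa_range_error")
})

test_that("profile metrics: step width, erf penumbra, Gaussian FWHM", {
  x <- seq(-80, 80, by = 0.1)
  step <- scan_profile(x, as.numeric(abs(x) <= 50) * 100 + 1e-9, axis = "crossplane")
  expect_equal(profile_metrics(step)$fwhm_mm, 100, tolerance = 0.2)

  erf_edge <- scan_profile(x, pnorm((50 - abs(x)) / 3), axis = "crossplane")
  m <- profile_metrics(erf_edge)
  expect_equal(m$penumbra_left_mm, 1.6832 * 3, tolerance = 0.05)
  expect_equal(m$penumbra_right_mm, 1.6832 * 3, tolerance = 0.05)

  gauss <- scan_profile(x, exp(-x^2 / (2 * 10^2)), axis = "inplane")
  expect_equal(profile_metrics(gauss)$fwhm_mm, 2 * sqrt(2 * log(2)) * 10, tolerance = 0.1)
})

test_that("profile metrics are invariant to uniform rescaling", {
  x <- seq(-40, 40, by = 0.2)
  v <- pnorm((20 - abs(x)) / 2.5)
  a <- profile_metrics(scan_profile(x, v, axis = "crossplane"))
  b <- profile_metrics(scan_profile(x, 17.3 * v, axis = "crossplane"))
  expect_equal(a$fwhm_mm, b$fwhm_mm)
  expect_equal(a$penumbra_left_mm, b$penumbra_left_mm)
})

test_that("profile without a 50% crossing raises a metric error", {
  x <- seq(-10, 10, by = 0.5)
  p <- scan_profile(x, 80 + 20 * exp(-x^2 / 50), axis = "crossplane")
  expect_error(profile_metrics(p), class = "linacqa_metric_error")
})

test_that("daisy-chaining reproduces the hand-worked example", {
  small <- detector_reading_table("SFD", c(5, 10, 30), c(0.40, 0.55, 0.80))
  ref <- detector_reading_table("CC13", c(30, 50, 100), c(0.81, 0.90, 1.00))
  of <- daisy_chain_output_factors(small, ref)
  expect_equal(of$factor[of$field_size_mm == 5], 0.405)
  # at the intermediate field the small detector cancels out
  expect_equal(of$factor[of$field_size_mm == 30], 0.81)
  expect_equal(of$factor[of$field_size_mm == 100], 1)
})

test_that("chained curve equals the reference-only curve when proportional", {
  fields <- c(5, 10, 20, 30, 50, 100)
  base <- c(0.5, 0.62, 0.74, 0.82, 0.9, 1.0)
  small <- detector_reading_table("d1", fields[1:4], 3.7 * base[1:4])
  ref <- detector_reading_table("d2", fields, base)
  of <- daisy_chain_output_factors(small, ref)
  expect_equal(of$factor, base / base[6], tolerance = 1e-12)
})

test_that("missing intermediate field raises a chaining error", {
  small <- detector_reading_table("d1", c(5, 10), c(0.4, 0.55))
  ref <- detector_reading_table("d2", c(30, 100), c(0.81, 1))
  expect_error(daisy_chain_output_factors(small, ref), class = "linacqa_chaining_error")
})

test_that("intermediate 20 vs 30 mm agree within the volume-averaging perturbation", {
  dr <- gen_detector_readings(field_sizes_mm = c(5, 10, 20, 30, 50, 100))
  of30 <- daisy_chain_output_factors(dr$tables$SFD, dr$tables$CC13, intermediate_mm = 30)
  of20 <- daisy_chain_output_factors(dr$tables$SFD, dr$tables$CC13, intermediate_mm = 20)
  f5_30 <- of30$factor[of30$field_size_mm == 5]
  f5_20 <- of20$factor[of20$field_size_mm == 5]
  expect_equal(f5_20, f5_30, tolerance = 0.03)
})

test_that("volume averaging lowers the chained small-field output factor", {
  dr <- gen_detector_readings()
  of_sfd <- daisy_chain_output_factors(dr$tables$SFD, dr$tables$CC13)
  of_cc13 <- daisy_chain_output_factors(dr$tables$CC13, dr$tables$CC13)
  expect_lt(of_cc13$factor[of_cc13$field_size_mm == 5],
            of_sfd$factor[of_sfd$field_size_mm == 5])
})

test_that("detector comparison reports pairwise differences and spread", {
  a <- daisy_chain_output_factors(
    detector_reading_table("a", c(5, 30), c(0.30, 0.80)),
    detector_reading_table("r", c(30, 100), c(0.80, 1)))
  b <- daisy_chain_output_factors(
    detector_reading_table("b", c(5, 30), c(0.62, 0.80)),
    detector_reading_table("r", c(30, 100), c(0.80, 1)))
  cmp <- compare_detectors(list(A = a, B = b))
  expect_equal(cmp$spread$abs_spread[cmp$spread$key == 5], 0.32)
  expect_equal(cmp$max_spread$key, 5)
  same <- compare_detectors(list(A = a, B = a))
  expect_true(all(same$pairwise$diff == 0))
  disjoint <- detector_reading_table("c", c(7, 40), c(0.5, 0.9))
  expect_error(compare_detectors(list(a, structure(data.frame(field_size_mm = c(7, 40),
                                                              factor = c(0.5, 0.9)),
                                                   class = c("output_factor_curve", "data.frame")))),
               class = "linacqa_comparison_error")
})
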