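# mlc_qa: picket fence, star shot, transmission, dynamic leaf gap.

test_that("picket fence recovers spacing, injected errors and FWHM", {
  r <- analyze_picket_fence(gen_picket_fence_image()$image, 30)
  expect_length(r$distances_mm, 4)
  expect_true(all(abs(r$distances_mm - 30) < 0.05))
  expect_lt(r$max_deviation_mm, 0.05)
  expect_true(all(abs(r$fwhm_mm - 2.2) < 0.1))

  r2 <- analyze_picket_fence(
    gen_picket_fence_image(per_picket_error_mm = c(0, 0, -0.5, 0, 0))$image, 30)
  expect_equal(r2$max_deviation_mm, 0.5, tolerance = 0.05)
})

test_that("picket positions are equivariant under whole-pixel translation", {
  g <- gen_picket_fence_image()
  img <- g$image
  k <- 7L
  shifted <- img
  shifted$pixels <- cbind(matrix(0.02, nrow(img$pixels), k),
                          img$pixels[, seq_len(ncol(img$pixels) - k)])
  a <- analyze_picket_fence(img, 30)$positions_mm
  b <- analyze_picket_fence(shifted, 30)$positions_mm
  expect_equal(b - a, rep(k * iso_pitch(img), length(a)), tolerance = 1e-6)
})

test_that("picket fence needs at least two bands", {
  g1 <- gen_picket_fence_image(n_pickets = 1)
  expect_error(analyze_picket_fence(g1$image, 30), class = "linacqa_detection_error")
})

test_that("star shot: concurrency, offset geometry, and error paths", {
  conc <- analyze_star_shot(gen_star_shot_image()$image)
  expect_lt(conc$circle$radius, 0.05)
  expect_true(conc$pass)

  # spokes at known perpendicular offsets: compare to the analytic circle
  angles <- c(0, 60, 120); offs <- c(0.6, -0.6, 0.6)
  g <- gen_star_shot_image(spoke_angles_deg = angles, spoke_offsets_mm = offs)
  th <- angles * pi / 180
  pts <- t(vapply(list(c(1, 2), c(1, 3), c(2, 3)), function(ij) {
    A <- rbind(c(-sin(th[ij[1]]), cos(th[ij[1]])), c(-sin(th[ij[2]]), cos(th[ij[2]])))
    as.numeric(solve(A, offs[ij]))
  }, numeric(2)))
  truth <- min_enclosing_circle(pts)
  res <- analyze_star_shot(g$image)
  expect_equal(res$circle$radius, truth$radius, tolerance = 0.1)
  expect_lt(sqrt(sum((res$circle$center - truth$center)^2)), 0.15)

  offc <- analyze_star_shot(gen_star_shot_image(spoke_angles_deg = c(0, 45, 90, 135),
                                                center_offset_mm = c(0.4, -0.3))$image)
  expect_lt(sqrt(sum((offc$circle$center - c(0.4, -0.3))^2)), 0.1)

  expect_error(
    analyze_star_shot(gen_star_shot_image(spoke_angles_deg = c(10, 190.000001),
                                          spoke_offsets_mm = c(8, -8))$image),
    class = "linacqa_error")
})

test_that("minimum enclosing circle matches the minimax oracle", {
  set.seed(31)
  for (k in 1:25) {
    n <- sample(2:12, 1)
    pts <- matrix(rnorm(2 * n, sd = 3), ncol = 2)
    got <- min_enclosing_circle(pts)
    ora <- mec_oracle(pts)
    expect_equal(got$radius, ora$radius, tolerance = 1e-5)
    # result must cover all points
    expect_true(all(sqrt((pts[, 1] - got$center[1])^2 +
                           (pts[, 2] - got$center[2])^2) <= got$radius + 1e-9))
  }
})

test_that("transmission ratio and acceptance flag", {
  r <- mlc_transmission(1.17, 100)
  expect_equal(r$transmission_pct, 1.17)
  expect_true(r$pass)
  expect_equal(mlc_transmission(0, 100)$transmission_pct, 0)
  r2 <- mlc_transmission(2.5, 100)
  expect_false(r2$pass)
  expect_error(mlc_transmission(1, 0), class = "linacqa_validation_error")
})

test_that("sweeping-gap worked example: intercept -0.72 mm gives delta 0.36 mm", {
  g <- gen_sweeping_gap_series(b = 0.02, delta_mm = 0.36, dleak_gy = 0.126,
                               gaps_mm = c(1, 5, 10, 20, 50, 100))
  fit <- fit_dynamic_leaf_gap(g$series)
  expect_equal(fit$x_intercept_mm, -0.72, tolerance = 1e-10)
  expect_equal(fit$delta_mm, 0.36, tolerance = 1e-10)
  expect_equal(fit$slope_b_gy_mm, 0.02, tolerance = 1e-10)

  g0 <- gen_sweeping_gap_series(delta_mm = 0)
  expect_equal(fit_dynamic_leaf_gap(g0$series)$delta_mm, 0, tolerance = 1e-10)
})

test_that("DLG fit is invariant to a common dose + Dleak offset", {
  g <- gen_sweeping_gap_series(noise_sigma = 0.0005, seed = 8)
  s2 <- sweeping_gap_series(g$series$gaps_mm, g$series$doses_gy + 0.5,
                            g$series$dleak_gy + 0.5)
  expect_equal(fit_dynamic_leaf_gap(g$series)$delta_mm,
               fit_dynamic_leaf_gap(s2)$delta_mm, tolerance = 1e-12)
})

test_that("noisy DLG recovery: mean delta within 0.02 mm over 50 seeds", {
  sigma <- 0.002 * max(gen_sweeping_gap_series()$series$doses_gy)  # 0.2% of max dose
  deltas <- vapply(1:50, function(s)
    fit_dynamic_leaf_gap(gen_sweeping_gap_series(noise_sigma = sigma, seed = s)$series)$delta_mm,
    numeric(1))
  expect_lt(abs(mean(deltas) - 0.36), 0.02)
})

test_that("series constructor enforces its invariants", {
  expect_error(sweeping_gap_series(c(5, 1), c(0.2, 0.3), 0.1),
               class = "linacqa_validation_error")
  expect_error(sweeping_gap_series(c(1, 5), c(0.05, 0.3), 0.1),
               class = "linacqa_validation_error")
  decreasing <- sweeping_gap_series(c(1, 5, 10), c(0.5, 0.4, 0.3), 0.1)
  expect_error(fit_dynamic_leaf_gap(decreasing), class = "linacqa_fit_error")
})
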