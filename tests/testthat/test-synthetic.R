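# synthetic_data: generator determinism, manifest echo, and model fidelity.

test_that("generators are pure functions of (params, seed)", {
  cases <- list(
    function() gen_bb_aperture_image(bb_offset_mm = c(0.3, -0.2), noise_sigma = 0.02, seed = 42),
    function() gen_picket_fence_image(noise_sigma = 0.01, seed = 42),
    function() gen_star_shot_image(noise_sigma = 0.01, seed = 42),
    function() gen_sweeping_gap_series(noise_sigma = 0.001, seed = 42),
    function() gen_dose_planes(noise_sigma = 1, seed = 42)
  )
  for (f in cases) {
    a <- f(); b <- f()
    pa <- if (!is.null(a$image)) a$image$pixels else if (!is.null(a$series)) a$series$doses_gy else a$eval$dose
    pb <- if (!is.null(b$image)) b$image$pixels else if (!is.null(b$series)) b$series$doses_gy else b$eval$dose
    expect_identical(pa, pb)
  }
  s1 <- gen_shift_samples(n = 50, seed = 9)$shifts
  s2 <- gen_shift_samples(n = 50, seed = 9)$shifts
  expect_identical(s1, s2)
})

test_that("generators leave the caller's RNG state untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(gen_bb_aperture_image(noise_sigma = 0.01, seed = 5))
  invisible(gen_shift_samples(n = 10, seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("BB/aperture generator echoes truth and respects symmetry", {
  g <- gen_bb_aperture_image(bb_offset_mm = c(0.35, 0.325))
  expect_equal(g$manifest$bb_offset_mm, c(0.35, 0.325))
  # noise-free centred BB: raster is left/right symmetric up to numerics
  g0 <- gen_bb_aperture_image(bb_offset_mm = c(0, 0))
  px <- g0$image$pixels
  expect_lt(max(abs(px - px[, rev(seq_len(ncol(px)))])), 1e-12)
  expect_lt(max(abs(px - px[rev(seq_len(nrow(px))), ])), 1e-12)
  expect_error(gen_bb_aperture_image(bb_offset_mm = c(5, 0)),
               class = "linacqa_generation_error")
})

test_that("picket-fence manifest records true gaps and deviations", {
  g <- gen_picket_fence_image(n_pickets = 5, spacing_mm = 30)
  expect_equal(g$manifest$gaps_mm, rep(30, 4))
  g1 <- gen_picket_fence_image(n_pickets = 1)
  expect_length(g1$manifest$positions_mm, 1)
  expect_length(g1$manifest$gaps_mm, 0)
  g2 <- gen_picket_fence_image(per_picket_error_mm = c(0, 0, 0.5, 0, 0))
  expect_equal(g2$manifest$max_deviation_mm, 0.5)
  expect_error(gen_picket_fence_image(spacing_mm = 2, picket_fwhm_mm = 2.2),
               class = "linacqa_generation_error")
})

test_that("star-shot generator echoes centre and rejects duplicate angles", {
  g <- gen_star_shot_image(center_offset_mm = c(0.4, -0.3))
  expect_equal(g$manifest$center_offset_mm, c(0.4, -0.3))
  expect_error(gen_star_shot_image(spoke_angles_deg = c(10, 190)),
               class = "linacqa_generation_error")
  expect_error(gen_star_shot_image(spoke_angles_deg = 45),
               class = "linacqa_generation_error")
})

test_that("sweeping-gap series follows the linear gap model exactly", {
  g <- gen_sweeping_gap_series(b = 0.02, delta_mm = 0.36, dleak_gy = 0.126,
                               gaps_mm = c(1, 5, 10, 20, 50, 100))
  expect_equal(g$series$doses_gy[1], 0.126 + 0.02 * (1 + 2 * 0.36))  # 0.1604 Gy
  # delta = 0: leakage-subtracted dose strictly proportional to gap
  g0 <- gen_sweeping_gap_series(delta_mm = 0)
  ratio <- (g0$series$doses_gy - g0$series$dleak_gy) / g0$series$gaps_mm
  expect_equal(max(ratio) - min(ratio), 0, tolerance = 1e-12)
  expect_error(gen_sweeping_gap_series(gaps_mm = 5), class = "linacqa_generation_error")
})

test_that("detector readings reproduce the disc-average oracle and its limits", {
  model <- small_field_model(sigma_mm = 1.5)
  out <- gen_detector_readings(model, detector_diameters_mm = c(tiny = 0.01, CC13 = 6),
                               field_sizes_mm = c(5, 30, 100))
  tiny <- out$tables$tiny
  # aperture -> 0 limit equals on-axis value
  expect_equal(tiny$reading, model(0, tiny$field_size_mm), tolerance = 1e-3)
  # large flat-top field: reading equals the plateau value
  cc13 <- out$tables$CC13
  expect_equal(cc13$reading[cc13$field_size_mm == 100], model(0, 100), tolerance = 1e-6)
  # 6 mm aperture on a 5 mm field: strict volume averaging, matches the 2D oracle
  r5 <- cc13$reading[cc13$field_size_mm == 5]
  expect_lt(r5, model(0, 5))
  expect_equal(r5, disc_average_oracle(model, 6, 5), tolerance = 1e-3)
  expect_true(any(grepl("CC13@5", out$manifest$aperture_warnings)))
})

test_that("dose-plane generator echoes its perturbations", {
  id <- gen_dose_planes()
  expect_identical(id$ref$dose, id$eval$dose)
  sc <- gen_dose_planes(scale_pct = 3)
  expect_equal(sc$eval$dose, sc$ref$dose * 1.03)
  expect_error(gen_dose_planes(grid_pitch_mm = 0), class = "linacqa_validation_error")
})

test_that("shift sampler matches its stated moments", {
  z <- gen_shift_samples(sigma_trans_mm = 0, sigma_rot_deg = 0, n = 5, seed = 3)$shifts
  expect_true(all(unlist(z) == 0))
  s <- gen_shift_samples(sigma_trans_mm = 1, sigma_rot_deg = 2, n = 4000, seed = 11)$shifts
  expect_equal(nrow(s), 4000)
  expect_equal(sd(s$dx), 1, tolerance = 0.05)
  expect_equal(sd(s$r_pa), 2, tolerance = 0.1)
  expect_equal(mean(s$dz), 0, tolerance = 0.06)
})
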