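# core_io: domain types, raster and table readers, geometry conventions.

test_that("planar_image validates its invariants", {
  px <- matrix(runif(16), 4)
  img <- planar_image(px, pixel_pitch_mm = 0.392, sdd_mm = 1500)
  expect_equal(magnification(img), 1.5)
  expect_equal(iso_pitch(img), 0.392 / 1.5)
  expect_error(planar_image(px, -0.1, 1500), class = "linacqa_validation_error")
  expect_error(planar_image(px, 0.392, sdd_mm = 900, sad_mm = 1000),
               class = "linacqa_validation_error")
  expect_error(planar_image(matrix(1, 1, 5), 0.392, 1500),
               class = "linacqa_validation_error")
  expect_error(planar_image(px - 1, 0.392, 1500), class = "linacqa_validation_error")
})

test_that("detector-to-isocenter conversion is linear in SDD", {
  px <- matrix(runif(64), 8)
  a <- planar_image(px, 0.4, sdd_mm = 1000, sad_mm = 1000)
  b <- planar_image(px, 0.4, sdd_mm = 2000, sad_mm = 1000)
  expect_equal(iso_pitch(a) / iso_pitch(b), 2)
})

test_that("PGM and CSV rasters round-trip bit-exactly with metadata", {
  img_int <- planar_image(matrix(sample.int(4096, 64 * 64, replace = TRUE) - 1L, 64),
                          pixel_pitch_mm = 0.392, sdd_mm = 1500, gantry_deg = 90)
  pgm <- withr::local_tempfile(fileext = ".pgm")
  write_planar_image(img_int, pgm)
  back <- read_planar_image(pgm)
  expect_identical(back$pixels, img_int$pixels)
  expect_equal(back$pixel_pitch_mm, 0.392, tolerance = 1e-6)
  expect_equal(back$gantry_deg, 90)

  img_real <- planar_image(matrix(runif(256), 16), 0.25, sdd_mm = 1200, table_deg = 45,
                           modality = "film")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_planar_image(img_real, csv)
  back2 <- read_planar_image(csv)
  expect_identical(back2$pixels, img_real$pixels)
  expect_identical(back2$table_deg, 45)
  expect_identical(back2$modality, "film")
})

test_that("meta argument fills and overrides geometry; missing pitch/SDD errors", {
  px <- matrix(sample.int(255, 32 * 32, replace = TRUE), 32)
  f <- withr::local_tempfile(fileext = ".pgm")
  writeLines(c("P2", "32 32", "255",
               paste(apply(px, 1, paste, collapse = " "), collapse = "\n")), f)
  expect_error(read_planar_image(f), class = "linacqa_config_error")
  img <- read_planar_image(f, meta = list(pixel_pitch_mm = 0.392, sdd_mm = 1500, sad_mm = 1000))
  expect_equal(magnification(img), 1.5)
  expect_equal(img$pixels, px, ignore_attr = TRUE)
})

test_that("unreadable and truncated files raise format errors", {
  f <- withr::local_tempfile(fileext = ".pgm")
  writeLines(c("P2", "8 8", "255", "1 2 3"), f)
  expect_error(read_planar_image(f, meta = list(pixel_pitch_mm = 1, sdd_mm = 1000)),
               class = "linacqa_format_error")
  expect_error(read_planar_image("no/such/file.pgm"), class = "linacqa_format_error")
  g <- withr::local_tempfile(fileext = ".csv")
  writeLines("not a raster", g)
  expect_error(read_planar_image(g), class = "linacqa_format_error")
})

test_that("scan profiles are grouped, sorted and renormalized to max 100", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(axis_tag = "depth", field_w = 100, field_h = 100, detector = "CC13",
                   position_mm = c(20, 0, 10), value = c(25, 50, 100))
  df2 <- data.frame(axis_tag = "crossplane", field_w = 50, field_h = 50, detector = "SFD",
                    position_mm = c(0, 10, 20), value = c(1, 2, 0.5))
  write.csv(rbind(df, df2), f, row.names = FALSE)
  ps <- read_scan_profiles(f)
  expect_length(ps, 2)
  depth <- ps[[which(vapply(ps, function(p) p$axis, "") == "depth")]]
  expect_equal(depth$positions_mm, c(0, 10, 20))
  expect_equal(depth$values, c(50, 100, 25))
  lat <- ps[[which(vapply(ps, function(p) p$axis, "") == "crossplane")]]
  expect_equal(lat$values, c(50, 100, 25))
})

test_that("profile reader rejects duplicates and empty files", {
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(axis_tag = "depth", field_w = 1, field_h = 1, detector = "d",
                       position_mm = c(0, 0, 5), value = c(1, 2, 3)), f, row.names = FALSE)
  expect_error(read_scan_profiles(f), class = "linacqa_validation_error")
  g <- withr::local_tempfile(fileext = ".csv")
  writeLines("axis_tag,field_w,field_h,detector,position_mm,value", g)
  expect_error(read_scan_profiles(g), class = "linacqa_validation_error")
})

test_that("shift log reader preserves order and names bad rows", {
  f <- withr::local_tempfile(fileext = ".csv")
  n <- 711
  set.seed(7)
  df <- data.frame(dx = rnorm(n), dy = rnorm(n), dz = rnorm(n),
                   r_lr = rnorm(n), r_pa = rnorm(n), r_si = rnorm(n))
  write.csv(df, f, row.names = FALSE)
  log <- read_shift_log(f)
  expect_equal(nrow(log), 711)
  expect_equal(log$dx, df$dx)

  df$dz[3] <- "NA"
  write.csv(df, f, row.names = FALSE)
  err <- tryCatch(read_shift_log(f), error = function(e) e)
  expect_s3_class(err, "linacqa_validation_error")
  expect_match(conditionMessage(err), "row 3")
})

test_that("single zero row parses to one identity shift", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("dx,dy,dz,r_lr,r_pa,r_si", "0,0,0,0,0,0"), f)
  log <- read_shift_log(f)
  expect_equal(nrow(log), 1)
  expect_true(all(unlist(log) == 0))
})
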