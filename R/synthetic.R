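# Seeded synthetic phantom-data generators. Each generator is a pure
# function of (parameters, seed): the caller's RNG state is saved and
# restored, and every output carries a ground-truth manifest so analysis
# operations can be tested as parameter-recovery problems.
#
# Intensity model: normalized [0, 1] scale; apertures are rendered as
# analytic blurred indicators (Gaussian edge blur in isocenter-plane mm,
# standing in for source penumbra), BBs as attenuation dips. Noise, when
# requested, is additive Gaussian on the normalized intensity.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Default EPID-like acquisition geometry
#'
#' Pixel pitch 0.392 mm at the detector, SDD 1500 mm, SAD 1000 mm
#' (magnification 1.5), i.e. an aSi MV portal imager.
#'
#' @return Named list with `pixel_pitch_mm`, `sdd_mm`, `sad_mm`.
#' @export
epid_geometry <- function() list(pixel_pitch_mm = 0.392, sdd_mm = 1500, sad_mm = 1000)

new_manifest <- function(generator, seed, params) {
  m <- c(list(generator = generator, seed = seed), params)
  class(m) <- "linacqa_manifest"
  m
}

#' @export
print.linacqa_manifest <- function(x, ...) {
  cat(jsonlite::toJSON(unclass(x), auto_unbox = TRUE, pretty = TRUE, digits = NA), "\n")
  invisible(x)
}

make_image <- function(pixels, geometry, gantry_deg = 0, table_deg = 0,
                       modality = "MV") {
  planar_image(pmax(pixels, 0), pixel_pitch_mm = geometry$pixel_pitch_mm,
               sdd_mm = geometry$sdd_mm, sad_mm = geometry$sad_mm,
               gantry_deg = gantry_deg, table_deg = table_deg,
               modality = modality)
}

# mm grids (isocenter plane, raster-centre origin) for a size_px = c(nr, nc)
# raster under `geometry`.
mm_grid <- function(size_px, geometry) {
  pitch <- geometry$pixel_pitch_mm / (geometry$sdd_mm / geometry$sad_mm)
  nr <- size_px[1]; nc <- size_px[2]
  list(x = (seq_len(nc) - 1 - (nc - 1) / 2) * pitch,
       y = (seq_len(nr) - 1 - (nr - 1) / 2) * pitch,
       pitch = pitch)
}

# Blurred 1D indicator of [-half, half] shifted to `centre`.
soft_slab <- function(u, centre, half, sigma) {
  if (sigma <= 0) return(as.numeric(abs(u - centre) <= half))
  stats::pnorm((u - centre + half) / sigma) - stats::pnorm((u - centre - half) / sigma)
}

#' Synthesize a Winston-Lutz BB-plus-aperture portal image
#'
#' Renders a bright open field (square MLC aperture or circular cone) with a
#' dark radio-opaque ball at a commanded sub-pixel offset, Gaussian edge
#' blur, and optional additive noise.
#'
#' @param bb_offset_mm Offset `c(x, y)` of the BB from the field centre, mm
#'   at the isocenter plane (left(-)/right(+), up(-)/down(+)).
#' @param aperture Either `list(shape = "square", width_mm =, height_mm =)`
#'   or `list(shape = "cone", diameter_mm =)`.
#' @param bb_diameter_mm BB diameter (default 5 mm).
#' @param field_offset_mm Offset of the field centre from the raster centre.
#' @param geometry Acquisition geometry (see [epid_geometry()]).
#' @param blur_sigma_mm Gaussian edge blur, isocenter-plane mm.
#' @param noise_sigma Additive Gaussian noise sd on the normalized intensity
#'   (plateau = 1); 0 disables noise.
#' @param size_px Raster size `c(rows, cols)`.
#' @param gantry_deg,table_deg Angle labels stored on the image.
#' @param seed RNG seed (used only when `noise_sigma > 0`).
#' @return `list(image = planar_image, manifest = ground-truth manifest)`.
#' @export
gen_bb_aperture_image <- function(bb_offset_mm = c(0, 0),
                                  aperture = list(shape = "square", width_mm = 15, height_mm = 15),
                                  bb_diameter_mm = 5,
                                  field_offset_mm = c(0, 0),
                                  geometry = epid_geometry(),
                                  blur_sigma_mm = 0.5,
                                  noise_sigma = 0,
                                  size_px = c(128, 128),
                                  gantry_deg = 0, table_deg = 0,
                                  seed = 1) {
  g <- mm_grid(size_px, geometry)
  baseline <- 0.05; plateau <- 1; bb_contrast <- 0.6
  r_bb <- bb_diameter_mm / 2
  margin <- r_bb + 3 * blur_sigma_mm
  rel <- bb_offset_mm - field_offset_mm  # BB relative to field centre
  if (identical(aperture$shape, "square")) {
    if (abs(rel[1]) + margin > aperture$width_mm / 2 ||
        abs(rel[2]) + margin > aperture$height_mm / 2)
      linacqa_error("linacqa_generation_error", "BB overlaps the field edge")
    fx <- soft_slab(g$x, field_offset_mm[1], aperture$width_mm / 2, blur_sigma_mm)
    fy <- soft_slab(g$y, field_offset_mm[2], aperture$height_mm / 2, blur_sigma_mm)
    field <- outer(fy, fx)
  } else if (identical(aperture$shape, "cone")) {
    if (sqrt(sum(rel^2)) + margin > aperture$diameter_mm / 2)
      linacqa_error("linacqa_generation_error", "BB overlaps the cone edge")
    r <- sqrt(outer((g$y - field_offset_mm[2])^2, (g$x - field_offset_mm[1])^2, `+`))
    field <- stats::pnorm((aperture$diameter_mm / 2 - r) / blur_sigma_mm)
  } else {
    linacqa_error("linacqa_validation_error", "aperture$shape must be 'square' or 'cone'")
  }
  rbbpx <- sqrt(outer((g$y - bb_offset_mm[2])^2, (g$x - bb_offset_mm[1])^2, `+`))
  # blurred disc indicator (vanishes as the diameter goes to zero)
  s_bb <- max(blur_sigma_mm, 0.2)
  bb <- stats::pnorm((r_bb - rbbpx) / s_bb) + stats::pnorm((r_bb + rbbpx) / s_bb) - 1
  px <- baseline + (plateau - baseline) * field * (1 - bb_contrast * bb)
  if (noise_sigma > 0)
    px <- px + with_seed(seed, matrix(stats::rnorm(length(px), 0, noise_sigma), nrow(px)))
  list(image = make_image(px, geometry, gantry_deg, table_deg),
       manifest = new_manifest("gen_bb_aperture_image", seed,
                               list(bb_offset_mm = bb_offset_mm,
                                    field_offset_mm = field_offset_mm,
                                    aperture = aperture,
                                    bb_diameter_mm = bb_diameter_mm,
                                    blur_sigma_mm = blur_sigma_mm,
                                    noise_sigma = noise_sigma,
                                    gantry_deg = gantry_deg, table_deg = table_deg)))
}

#' Synthesize a picket-fence EPID image
#'
#' Bright narrow Gaussian bands (pickets) at nominally equal spacing along
#' the leaf-travel (x) axis, with optional per-picket position errors.
#'
#' @param n_pickets Number of pickets (default 5).
#' @param spacing_mm Nominal interline distance at the isocenter (default
#'   30 mm).
#' @param picket_fwhm_mm Full width at half maximum of each band (default
#'   2.2 mm).
#' @param per_picket_error_mm Scalar or length-`n_pickets` vector of injected
#'   position errors, mm.
#' @param geometry,noise_sigma,seed As in [gen_bb_aperture_image()].
#' @param height_px Raster rows (bands run vertically).
#' @return `list(image, manifest)`; the manifest holds the true picket
#'   positions and inter-picket gaps.
#' @export
gen_picket_fence_image <- function(n_pickets = 5, spacing_mm = 30,
                                   picket_fwhm_mm = 2.2,
                                   per_picket_error_mm = 0,
                                   geometry = epid_geometry(),
                                   noise_sigma = 0, height_px = 48,
                                   seed = 1) {
  if (n_pickets < 1) linacqa_error("linacqa_generation_error", "need at least one picket")
  if (n_pickets > 1 && spacing_mm <= picket_fwhm_mm)
    linacqa_error("linacqa_generation_error", "spacing must exceed the picket width")
  err <- rep_len(per_picket_error_mm, n_pickets)
  pos <- (seq_len(n_pickets) - (n_pickets + 1) / 2) * spacing_mm + err
  span <- if (n_pickets > 1) (n_pickets - 1) * spacing_mm else 0
  pitch_iso <- geometry$pixel_pitch_mm / (geometry$sdd_mm / geometry$sad_mm)
  width_px <- ceiling((span + 8 * picket_fwhm_mm + 10) / pitch_iso)
  g <- mm_grid(c(height_px, width_px), geometry)
  sig <- picket_fwhm_mm / (2 * sqrt(2 * log(2)))
  prof <- rep(0.02, width_px)
  for (p in pos) prof <- prof + 0.9 * exp(-(g$x - p)^2 / (2 * sig^2))
  px <- matrix(prof, nrow = height_px, ncol = width_px, byrow = TRUE)
  if (noise_sigma > 0)
    px <- px + with_seed(seed, matrix(stats::rnorm(length(px), 0, noise_sigma), height_px))
  list(image = make_image(px, geometry),
       manifest = new_manifest("gen_picket_fence_image", seed,
                               list(n_pickets = n_pickets, spacing_mm = spacing_mm,
                                    picket_fwhm_mm = picket_fwhm_mm,
                                    per_picket_error_mm = err,
                                    positions_mm = pos,
                                    gaps_mm = if (n_pickets > 1) diff(pos) else numeric(0),
                                    max_deviation_mm = max(abs(err - stats::median(err))),
                                    noise_sigma = noise_sigma)))
}

#' Synthesize a star-shot (spoke-shot) film image
#'
#' Dark narrow slit lines at the given angles. Each spoke is a full line at
#' signed perpendicular distance `spoke_offsets_mm[i]` from the common
#' centre, so non-concurrent spoke sets (finite wobble circles) can be
#' produced with known geometry.
#'
#' @param spoke_angles_deg Line angles in degrees from the +x axis, distinct
#'   modulo 180.
#' @param center_offset_mm Common centre `c(x, y)` offset from the raster
#'   centre, mm.
#' @param spoke_offsets_mm Scalar or per-spoke signed perpendicular offset of
#'   each line from the centre, mm (0 = concurrent spokes).
#' @param slit_width_mm FWHM of each slit line.
#' @param geometry Film-like geometry default: 0.3 mm pitch at magnification 1.
#' @param size_px,noise_sigma,seed As elsewhere.
#' @return `list(image, manifest)`.
#' @export
gen_star_shot_image <- function(spoke_angles_deg = c(0, 60, 120),
                                center_offset_mm = c(0, 0),
                                spoke_offsets_mm = 0,
                                slit_width_mm = 1.2,
                                geometry = list(pixel_pitch_mm = 0.3, sdd_mm = 1000, sad_mm = 1000),
                                size_px = c(220, 220),
                                noise_sigma = 0, seed = 1) {
  n <- length(spoke_angles_deg)
  if (n < 2) linacqa_error("linacqa_generation_error", "need at least two spokes")
  am <- spoke_angles_deg %% 180
  sep <- abs(outer(am, am, `-`))
  sep <- pmin(sep, 180 - sep) + diag(Inf, n)
  if (min(sep) < 1e-9)
    linacqa_error("linacqa_generation_error", "duplicate spoke angles modulo 180 degrees")
  off <- rep_len(spoke_offsets_mm, n)
  g <- mm_grid(size_px, geometry)
  X <- matrix(g$x, size_px[1], size_px[2], byrow = TRUE) - center_offset_mm[1]
  Y <- matrix(g$y, size_px[1], size_px[2]) - center_offset_mm[2]
  sig <- slit_width_mm / (2 * sqrt(2 * log(2)))
  px <- matrix(1, size_px[1], size_px[2])
  th <- spoke_angles_deg * pi / 180
  for (i in seq_len(n)) {
    d <- abs(-sin(th[i]) * X + cos(th[i]) * Y - off[i])
    px <- px * (1 - 0.85 * exp(-d^2 / (2 * sig^2)))
  }
  if (noise_sigma > 0)
    px <- px + with_seed(seed, matrix(stats::rnorm(length(px), 0, noise_sigma), size_px[1]))
  list(image = make_image(px, geometry, modality = "film"),
       manifest = new_manifest("gen_star_shot_image", seed,
                               list(spoke_angles_deg = spoke_angles_deg,
                                    center_offset_mm = center_offset_mm,
                                    spoke_offsets_mm = off,
                                    slit_width_mm = slit_width_mm,
                                    noise_sigma = noise_sigma)))
}

#' Synthesize a sweeping-gap dose series
#'
#' Doses follow the linear sweeping-gap model
#' `D = Dleak + b * (gap + 2 * delta)` with optional additive Gaussian noise,
#' emulating the dynamic-leaf-gap measurement.
#'
#' @param b Dose per unit gap, Gy/mm.
#' @param delta_mm True dynamic leaf shift, mm.
#' @param dleak_gy Leakage dose measured with all leaves closed, Gy.
#' @param gaps_mm Nominal gaps, mm (default the standard 1, 5, 10, 20, 50,
#'   100 mm series).
#' @param noise_sigma Additive dose noise sd, Gy.
#' @param seed RNG seed.
#' @return `list(series = sweeping_gap_series, manifest)`.
#' @export
gen_sweeping_gap_series <- function(b = 0.02, delta_mm = 0.36, dleak_gy = 0.126,
                                    gaps_mm = c(1, 5, 10, 20, 50, 100),
                                    noise_sigma = 0, seed = 1) {
  if (length(unique(gaps_mm)) < 2)
    linacqa_error("linacqa_generation_error", "need at least two distinct gaps")
  if (any(gaps_mm <= 0))
    linacqa_error("linacqa_generation_error", "gaps must be positive")
  gaps <- sort(gaps_mm)
  doses <- dleak_gy + b * (gaps + 2 * delta_mm)
  if (noise_sigma > 0)
    doses <- doses + with_seed(seed, stats::rnorm(length(gaps), 0, noise_sigma))
  list(series = sweeping_gap_series(gaps, doses, dleak_gy),
       manifest = new_manifest("gen_sweeping_gap_series", seed,
                               list(b = b, delta_mm = delta_mm, dleak_gy = dleak_gy,
                                    gaps_mm = gaps, noise_sigma = noise_sigma)))
}

#' Default radially symmetric small-field fluence model
#'
#' Returns a function `f(r_mm, field_mm)` giving relative dose at off-axis
#' radius `r` for a square field of side `field_mm`: a flat top with
#' Gaussian-blurred shoulders (penumbra sigma `sigma_mm`) scaled by a
#' saturating output-factor curve, so smaller fields have both lower output
#' and proportionally narrower plateaus.
#'
#' @param sigma_mm Penumbra sigma, mm (default 1.5; the true penumbra of the
#'   beam is not a claim of this generator, only a fixture choice).
#' @return Function of `(r_mm, field_mm)`.
#' @export
small_field_model <- function(sigma_mm = 1.5) {
  function(r_mm, field_mm) {
    of <- 1 - 0.55 * exp(-field_mm / 18)
    of * stats::pnorm((field_mm / 2 - r_mm) / sigma_mm)
  }
}

#' Synthesize detector readings with volume averaging
#'
#' The reading of a detector of active diameter `d` for field size `f` is the
#' mean of the radial fluence model over a disc of diameter `d` centred on
#' the beam axis, computed by numerical integration. Small apertures
#' approach the on-axis point dose; large apertures average the penumbra in.
#'
#' @param model Fluence model `f(r_mm, field_mm)` (default
#'   [small_field_model()]).
#' @param detector_diameters_mm Active diameters, mm; names become detector
#'   ids (defaults mirror a stereotactic diode, a small and a medium ion
#'   chamber: 0.6, 2, 6 mm).
#' @param field_sizes_mm Square field sides, mm.
#' @return `list(tables = named list of detector_reading_table, manifest)`;
#'   the manifest flags detectors whose aperture exceeds a field.
#' @export
gen_detector_readings <- function(model = small_field_model(),
                                  detector_diameters_mm = c(SFD = 0.6, CC01 = 2, CC13 = 6),
                                  field_sizes_mm = c(5, 10, 20, 30, 50, 100)) {
  if (any(detector_diameters_mm <= 0))
    linacqa_error("linacqa_validation_error", "aperture diameters must be positive")
  ids <- names(detector_diameters_mm)
  if (is.null(ids)) ids <- sprintf("det%g", detector_diameters_mm)
  warn <- character(0)
  tables <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_along(ids)) {
    R <- detector_diameters_mm[[i]] / 2
    readings <- vapply(sort(field_sizes_mm), function(f) {
      if (detector_diameters_mm[[i]] > f) warn <<- c(warn, sprintf("%s@%g", ids[i], f))
      # disc mean of a radial function: (2/R^2) * int_0^R f(r) r dr
      (2 / R^2) * stats::integrate(function(r) model(r, f) * r, 0, R,
                                   rel.tol = 1e-10)$value
    }, numeric(1))
    tables[[i]] <- detector_reading_table(ids[i], sort(field_sizes_mm), readings)
  }
  list(tables = tables,
       manifest = new_manifest("gen_detector_readings", NULL,
                               list(detector_diameters_mm = as.list(detector_diameters_mm),
                                    field_sizes_mm = sort(field_sizes_mm),
                                    aperture_warnings = warn)))
}

#' Synthesize a pair of registered planar dose grids
#'
#' The reference is an analytic plan-like dose (background + blurred
#' high-dose disc). The evaluated grid is the same analytic dose with
#' controlled perturbations: a uniform percent scaling, a rigid in-plane
#' shift (applied analytically, no resampling), and additive noise.
#'
#' @param grid_pitch_mm Grid spacing, mm.
#' @param size_px Grid size `c(rows, cols)`.
#' @param scale_pct Uniform dose perturbation, percent.
#' @param shift_mm In-plane shift `c(x, y)` of the evaluated dose, mm.
#' @param noise_sigma Additive noise sd, cGy.
#' @param plateau_cgy,radius_mm,penumbra_mm,background_cgy Plan-shape knobs.
#' @param seed RNG seed.
#' @return `list(ref = dose_grid, eval = dose_grid, manifest)`.
#' @export
gen_dose_planes <- function(grid_pitch_mm = 1, size_px = c(64, 64),
                            scale_pct = 0, shift_mm = c(0, 0), noise_sigma = 0,
                            plateau_cgy = 200, radius_mm = 15, penumbra_mm = 3,
                            background_cgy = 5, seed = 1) {
  if (grid_pitch_mm <= 0)
    linacqa_error("linacqa_validation_error", "grid pitch must be positive")
  base <- function(x, y) {
    r <- sqrt(outer(y^2, x^2, `+`))
    background_cgy + (plateau_cgy - background_cgy) *
      stats::pnorm((radius_mm - r) / penumbra_mm)
  }
  nr <- size_px[1]; nc <- size_px[2]
  x <- (seq_len(nc) - 1 - (nc - 1) / 2) * grid_pitch_mm
  y <- (seq_len(nr) - 1 - (nr - 1) / 2) * grid_pitch_mm
  ref <- base(x, y)
  ev <- base(x - shift_mm[1], y - shift_mm[2]) * (1 + scale_pct / 100)
  if (noise_sigma > 0)
    ev <- ev + with_seed(seed, matrix(stats::rnorm(length(ev), 0, noise_sigma), nr))
  list(ref = dose_grid(ref, grid_pitch_mm),
       eval = dose_grid(pmax(ev, 0), grid_pitch_mm),
       manifest = new_manifest("gen_dose_planes", seed,
                               list(grid_pitch_mm = grid_pitch_mm, size_px = size_px,
                                    scale_pct = scale_pct, shift_mm = shift_mm,
                                    noise_sigma = noise_sigma)))
}

#' Synthesize 6-DOF setup-error samples
#'
#' Independent zero-mean Gaussian translations and rotations, emulating
#' per-fraction image-registration corrections.
#'
#' @param sigma_trans_mm Translation sd, mm (scalar or length 3).
#' @param sigma_rot_deg Rotation sd, degrees (scalar or length 3).
#' @param n Number of samples.
#' @param seed RNG seed.
#' @return `list(shifts = data.frame(dx, dy, dz, r_lr, r_pa, r_si), manifest)`.
#' @export
gen_shift_samples <- function(sigma_trans_mm = 0.5, sigma_rot_deg = 0.8, n = 100,
                              seed = 1) {
  if (n < 1) linacqa_error("linacqa_validation_error", "n must be >= 1")
  if (any(c(sigma_trans_mm, sigma_rot_deg) < 0))
    linacqa_error("linacqa_validation_error", "sigmas must be non-negative")
  st <- rep_len(sigma_trans_mm, 3); sr <- rep_len(sigma_rot_deg, 3)
  shifts <- with_seed(seed, data.frame(
    dx = stats::rnorm(n, 0, st[1]), dy = stats::rnorm(n, 0, st[2]),
    dz = stats::rnorm(n, 0, st[3]), r_lr = stats::rnorm(n, 0, sr[1]),
    r_pa = stats::rnorm(n, 0, sr[2]), r_si = stats::rnorm(n, 0, sr[3])))
  list(shifts = shifts,
       manifest = new_manifest("gen_shift_samples", seed,
                               list(sigma_trans_mm = st, sigma_rot_deg = sr, n = n)))
}

#' Synthesize a line-pair resolution phantom image
#'
#' One horizontal band per frequency group, each containing vertical bars at
#' the group's spatial frequency, blurred with a known Gaussian PSF. The
#' blurred square wave is rendered analytically (sum of error-function
#' edges), so the modulation oracle is exact up to sampling.
#'
#' @param frequencies_lp_mm Group frequencies, line pairs per mm.
#' @param psf_sigma_mm Gaussian PSF sigma, mm.
#' @param periods_per_group Full bar periods per group (>= 2).
#' @param geometry Imager geometry; default a kV panel at magnification 1
#'   (0.194 mm pitch).
#' @param noise_sigma,seed As elsewhere.
#' @return `list(image, rois, manifest)`; `rois` is a list of
#'   `list(rows, cols, frequency_lp_mm)` entries suitable for
#'   [compute_rmtf()].
#' @export
gen_line_pair_image <- function(frequencies_lp_mm = c(0.5, 0.71, 1, 1.4, 2, 2.8, 4),
                                psf_sigma_mm = 0.2, periods_per_group = 4,
                                geometry = list(pixel_pitch_mm = 0.194, sdd_mm = 1000, sad_mm = 1000),
                                noise_sigma = 0, seed = 1) {
  if (periods_per_group < 2)
    linacqa_error("linacqa_validation_error", "need at least two periods per group")
  freqs <- sort(frequencies_lp_mm)
  pitch <- geometry$pixel_pitch_mm / (geometry$sdd_mm / geometry$sad_mm)
  band_px <- 24L; gap_px <- 6L
  widest_mm <- periods_per_group / min(freqs) + 6
  nc <- ceiling(widest_mm / pitch)
  nr <- length(freqs) * (band_px + gap_px) + gap_px
  x <- (seq_len(nc) - 1) * pitch
  px <- matrix(0.2, nr, nc)
  rois <- vector("list", length(freqs))
  lo <- 0.2; hi <- 0.8
  for (i in seq_along(freqs)) {
    p <- 1 / freqs[i]                       # one line pair = one period
    x0 <- 3                                  # leading margin, mm
    prof <- rep(lo, nc)
    for (k in seq_len(periods_per_group)) {
      a <- x0 + (k - 1) * p; bnd <- a + p / 2
      prof <- prof + (hi - lo) *
        (stats::pnorm((x - a) / psf_sigma_mm) - stats::pnorm((x - bnd) / psf_sigma_mm))
    }
    r0 <- gap_px + (i - 1) * (band_px + gap_px) + 1L
    rows <- r0:(r0 + band_px - 1L)
    px[rows, ] <- matrix(prof, length(rows), nc, byrow = TRUE)
    cols <- max(1L, floor((x0 - 1) / pitch)):min(nc, ceiling((x0 + periods_per_group * p + 1) / pitch))
    rois[[i]] <- list(rows = c(r0, r0 + band_px - 1L),
                      cols = c(min(cols), max(cols)),
                      frequency_lp_mm = freqs[i])
  }
  if (noise_sigma > 0)
    px <- px + with_seed(seed, matrix(stats::rnorm(length(px), 0, noise_sigma), nr))
  list(image = make_image(px, geometry, modality = "kV"),
       rois = rois,
       manifest = new_manifest("gen_line_pair_image", seed,
                               list(frequencies_lp_mm = freqs, psf_sigma_mm = psf_sigma_mm,
                                    periods_per_group = periods_per_group,
                                    noise_sigma = noise_sigma)))
}
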