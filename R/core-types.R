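# Shared domain types and coordinate conventions.
#
# Conventions used throughout the package:
#   * pixel coordinates are 0-based and refer to pixel centres;
#   * raster axes follow the beam's-eye view at collimator 0: x increases to
#     the viewer's right (columns), y increases downwards (rows);
#   * reported distances are isocenter-plane millimetres, i.e. detector-plane
#     mm divided by the magnification SDD/SAD;
#   * planar offsets use the portal-image convention left(-)/right(+) for x
#     and up(-)/down(+) for y, which coincides with the raster axes above.

linacqa_error <- function(class, message, ...) {
  stop(structure(
    class = c(class, "linacqa_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

#' Calibrated planar image
#'
#' A 2D grayscale raster with the acquisition geometry needed to convert
#' detector-plane pixels to isocenter-plane millimetres. This is the common
#' container for portal (MV), kV and digitised film images.
#'
#' @param pixels Numeric matrix of non-negative intensities (rows = y,
#'   columns = x).
#' @param pixel_pitch_mm Pixel pitch at the detector plane, mm/pixel.
#' @param sdd_mm Source-to-detector distance, mm.
#' @param sad_mm Source-to-axis distance, mm (default 1000).
#' @param gantry_deg,collimator_deg,table_deg Acquisition angles in degrees.
#' @param modality One of `"MV"`, `"kV"`, `"film"`.
#'
#' @return An object of class `planar_image`.
#' @export
planar_image <- function(pixels, pixel_pitch_mm, sdd_mm, sad_mm = 1000,
                         gantry_deg = 0, collimator_deg = 0, table_deg = 0,
                         modality = c("MV", "kV", "film")) {
  modality <- match.arg(modality)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    linacqa_error("linacqa_validation_error", "'pixels' must be a numeric matrix")
  if (nrow(pixels) < 2L || ncol(pixels) < 2L)
    linacqa_error("linacqa_validation_error", "raster must have at least 2 rows and 2 columns")
  if (any(!is.finite(pixels)) || any(pixels < 0))
    linacqa_error("linacqa_validation_error", "pixel values must be finite and non-negative")
  if (!is.numeric(pixel_pitch_mm) || length(pixel_pitch_mm) != 1L || pixel_pitch_mm <= 0)
    linacqa_error("linacqa_validation_error", "'pixel_pitch_mm' must be a positive scalar")
  if (!is.numeric(sad_mm) || sad_mm <= 0 || !is.numeric(sdd_mm) || sdd_mm < sad_mm)
    linacqa_error("linacqa_validation_error",
                  "'sdd_mm' must satisfy sdd_mm >= sad_mm > 0")
  structure(
    list(pixels = pixels,
         pixel_pitch_mm = as.numeric(pixel_pitch_mm),
         sdd_mm = as.numeric(sdd_mm),
         sad_mm = as.numeric(sad_mm),
         gantry_deg = as.numeric(gantry_deg),
         collimator_deg = as.numeric(collimator_deg),
         table_deg = as.numeric(table_deg),
         modality = modality),
    class = "planar_image"
  )
}

#' @export
print.planar_image <- function(x, ...) {
  cat(sprintf("<planar_image> %d x %d px, pitch %.4g mm (%.4g mm at iso), %s, G%g C%g T%g\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_pitch_mm, iso_pitch(x),
              x$modality, x$gantry_deg, x$collimator_deg, x$table_deg))
  invisible(x)
}

#' Imaging magnification SDD/SAD
#' @param image A [planar_image].
#' @return Magnification factor (>= 1).
#' @export
magnification <- function(image) image$sdd_mm / image$sad_mm

#' Pixel pitch projected to the isocenter plane
#' @param image A [planar_image].
#' @return mm per pixel at the isocenter plane.
#' @export
iso_pitch <- function(image) image$pixel_pitch_mm / magnification(image)

# Isocenter-plane mm coordinates of pixel centres. x along columns
# (positive right), y along rows (positive down); (0, 0) is raster centre.
iso_coords <- function(image) {
  p <- iso_pitch(image)
  nr <- nrow(image$pixels); nc <- ncol(image$pixels)
  list(x = (seq_len(nc) - 1 - (nc - 1) / 2) * p,
       y = (seq_len(nr) - 1 - (nr - 1) / 2) * p)
}

#' 2D point / offset at the isocenter plane
#'
#' Named numeric pair in isocenter-plane millimetres, x left(-)/right(+),
#' y up(-)/down(+).
#'
#' @param x,y Coordinates in mm.
#' @return Named numeric vector `c(x =, y =)`.
#' @export
point2d <- function(x, y) {
  if (!is.finite(x) || !is.finite(y))
    linacqa_error("linacqa_validation_error", "point coordinates must be finite")
  c(x = as.numeric(x), y = as.numeric(y))
}

#' Six degree-of-freedom shift
#'
#' Translations along the patient left/right, posterior/anterior and
#' superior/inferior axes (mm) and rotations about those axes (degrees).
#'
#' @param dx,dy,dz Translations in mm.
#' @param r_lr,r_pa,r_si Rotations in degrees, each in (-180, 180].
#' @return Named numeric vector of class `sixdof_shift`.
#' @export
sixdof_shift <- function(dx = 0, dy = 0, dz = 0, r_lr = 0, r_pa = 0, r_si = 0) {
  v <- c(dx = dx, dy = dy, dz = dz, r_lr = r_lr, r_pa = r_pa, r_si = r_si)
  if (any(!is.finite(v)))
    linacqa_error("linacqa_validation_error", "shift components must be finite")
  rot <- v[c("r_lr", "r_pa", "r_si")]
  if (any(rot <= -180 | rot > 180))
    linacqa_error("linacqa_validation_error", "rotations must lie in (-180, 180] degrees")
  structure(as.numeric(v), names = names(v), class = "sixdof_shift")
}

#' Scanned beam profile
#'
#' A 1D dose scan: depth scan (PDD) or lateral (in-plane/cross-plane)
#' profile. Values are renormalized so the maximum is 100.
#'
#' @param positions_mm Strictly increasing scan positions (depth or off-axis
#'   distance), mm.
#' @param values Non-negative relative dose values.
#' @param axis One of `"depth"`, `"inplane"`, `"crossplane"`.
#' @param field_mm Field size `c(width, height)` in mm.
#' @param detector Detector label.
#' @return Object of class `scan_profile` with `values` scaled to max 100.
#' @export
scan_profile <- function(positions_mm, values, axis = c("depth", "inplane", "crossplane"),
                         field_mm = c(NA_real_, NA_real_), detector = "") {
  axis <- match.arg(axis)
  if (length(positions_mm) != length(values) || length(values) < 2L)
    linacqa_error("linacqa_validation_error",
                  "positions and values must have equal length >= 2")
  if (any(!is.finite(positions_mm)) || any(diff(positions_mm) <= 0))
    linacqa_error("linacqa_validation_error", "positions must be strictly increasing")
  if (any(!is.finite(values)) || any(values < 0) || max(values) <= 0)
    linacqa_error("linacqa_validation_error", "values must be non-negative with a positive maximum")
  structure(
    list(positions_mm = as.numeric(positions_mm),
         values = 100 * as.numeric(values) / max(values),
         axis = axis,
         field_mm = as.numeric(field_mm),
         detector = as.character(detector)),
    class = "scan_profile"
  )
}
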