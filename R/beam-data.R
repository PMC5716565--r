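# Scanned beam-data reduction: PDD queries, lateral profile metrics, and
# small-field output-factor daisy-chaining across detectors.

#' Detector reading table
#'
#' Per-field-size readings for one detector, used for output-factor
#' daisy-chaining.
#'
#' @param detector_id Detector label.
#' @param field_size_mm Square field sides, mm (unique).
#' @param reading Positive readings, arbitrary units.
#' @return Object of class `detector_reading_table` (a data.frame sorted by
#'   field size, with attribute `detector_id`).
#' @export
detector_reading_table <- function(detector_id, field_size_mm, reading) {
  if (length(field_size_mm) != length(reading))
    linacqa_error("linacqa_validation_error", "field sizes and readings must match in length")
  if (anyDuplicated(field_size_mm))
    linacqa_error("linacqa_validation_error", "field sizes must be unique")
  if (any(reading <= 0))
    linacqa_error("linacqa_validation_error", "readings must be positive")
  ord <- order(field_size_mm)
  structure(data.frame(field_size_mm = field_size_mm[ord], reading = reading[ord]),
            detector_id = as.character(detector_id),
            class = c("detector_reading_table", "data.frame"))
}

table_reading <- function(tbl, f) {
  i <- which(abs(tbl$field_size_mm - f) < 1e-9)
  if (length(i) != 1L)
    linacqa_error("linacqa_chaining_error",
                  sprintf("detector '%s' has no reading for field %g mm",
                          attr(tbl, "detector_id"), f))
  tbl$reading[i]
}

#' Percent depth dose at a depth
#'
#' Linear interpolation on a max-normalized depth profile.
#'
#' @param profile A [scan_profile] with `axis == "depth"`.
#' @param depth_mm Query depth, mm; must lie within the scanned range.
#' @return PDD in percent (maximum of the curve is 100).
#' @export
pdd_at_depth <- function(profile, depth_mm) {
  stopifnot(inherits(profile, "scan_profile"))
  if (profile$axis != "depth")
    linacqa_error("linacqa_validation_error", "PDD query requires a depth-axis profile")
  rng <- range(profile$positions_mm)
  if (depth_mm < rng[1] || depth_mm > rng[2])
    linacqa_error("linacqa_range_error",
                  sprintf("depth %g mm outside scanned range [%g, %g]", depth_mm, rng[1], rng[2]))
  stats::approx(profile$positions_mm, profile$values, xout = depth_mm)$y
}

#' Lateral profile metrics: FWHM and 80-20% penumbrae
#'
#' Percent levels are taken relative to the central-axis (position 0) value,
#' not the global maximum, so off-axis horns do not bias the penumbra.
#' Crossings are the outermost sub-pixel linear interpolations at each
#' level.
#'
#' @param profile A lateral [scan_profile] crossing 50% on both sides.
#' @return `list(fwhm_mm, penumbra_left_mm, penumbra_right_mm,
#'   edges_mm = c(left50, right50))`.
#' @export
profile_metrics <- function(profile) {
  stopifnot(inherits(profile, "scan_profile"))
  if (profile$axis == "depth")
    linacqa_error("linacqa_validation_error", "profile metrics require a lateral profile")
  cax <- stats::approx(profile$positions_mm, profile$values, xout = 0)$y
  if (is.na(cax) || cax <= 0)
    linacqa_error("linacqa_metric_error", "no central-axis value (position 0 not in range)")
  cross <- lapply(c(0.5, 0.8, 0.2), function(fr)
    outer_crossings(profile$positions_mm, profile$values, fr * cax))
  if (any(vapply(cross, is.null, logical(1))))
    linacqa_error("linacqa_metric_error", "profile does not cross a required level on both sides")
  c50 <- cross[[1]]; c80 <- cross[[2]]; c20 <- cross[[3]]
  list(fwhm_mm = c50[2] - c50[1],
       penumbra_left_mm = abs(c20[1] - c80[1]),
       penumbra_right_mm = abs(c20[2] - c80[2]),
       edges_mm = c50)
}

#' Daisy-chain small-field output factors across detectors
#'
#' For fields smaller than the intermediate size, the small detector's
#' readings are normalized at the intermediate field and re-anchored to the
#' reference detector:
#' `OF(f) = D(f)/D(mid) * Ref(mid)/Ref(ref)`.
#' For fields at or above the intermediate size, the reference detector's
#' ratio `Ref(f)/Ref(ref)` is used directly.
#'
#' @param small_detector,reference_detector [detector_reading_table]s; the
#'   small detector must include the intermediate field, the reference
#'   detector the intermediate and reference fields.
#' @param intermediate_mm Intermediate (hand-over) field side, mm
#'   (default 30).
#' @param reference_mm Reference field side, mm (default 100).
#' @return Object of class `output_factor_curve`: data.frame
#'   `(field_size_mm, factor)` with the factor at the reference field equal
#'   to 1 when present.
#' @export
daisy_chain_output_factors <- function(small_detector, reference_detector,
                                       intermediate_mm = 30, reference_mm = 100) {
  d_mid <- table_reading(small_detector, intermediate_mm)
  r_mid <- table_reading(reference_detector, intermediate_mm)
  r_ref <- table_reading(reference_detector, reference_mm)
  small_f <- small_detector$field_size_mm[small_detector$field_size_mm < intermediate_mm]
  large_f <- reference_detector$field_size_mm[reference_detector$field_size_mm >= intermediate_mm]
  fields <- sort(unique(c(small_f, large_f)))
  factor <- vapply(fields, function(f) {
    if (f < intermediate_mm)
      table_reading(small_detector, f) / d_mid * r_mid / r_ref
    else
      table_reading(reference_detector, f) / r_ref
  }, numeric(1))
  structure(data.frame(field_size_mm = fields, factor = factor),
            intermediate_mm = intermediate_mm, reference_mm = reference_mm,
            class = c("output_factor_curve", "data.frame"))
}

#' Compare detector curves
#'
#' Pairwise percent differences per common field size (or scan position)
#' across output-factor curves or scan profiles, plus the absolute spread
#' (max - min) at each common point; the largest spread is flagged.
#'
#' @param curves Named list of [output_factor_curve]s (or [scan_profile]s).
#' @return `list(pairwise = data.frame, spread = data.frame,
#'   max_spread)`.
#' @export
compare_detectors <- function(curves) {
  if (length(curves) < 2L)
    linacqa_error("linacqa_validation_error", "need at least two curves to compare")
  nm <- names(curves)
  if (is.null(nm)) nm <- paste0("curve", seq_along(curves))
  kv <- lapply(curves, function(cu) {
    if (inherits(cu, "output_factor_curve"))
      list(key = cu$field_size_mm, value = cu$factor)
    else if (inherits(cu, "scan_profile"))
      list(key = cu$positions_mm, value = cu$values)
    else if (is.data.frame(cu) && ncol(cu) >= 2L)
      list(key = cu[[1]], value = cu[[2]])
    else linacqa_error("linacqa_validation_error", "unsupported curve type")
  })
  common <- Reduce(intersect, lapply(kv, `[[`, "key"))
  if (length(common) == 0L)
    linacqa_error("linacqa_comparison_error", "curves share no common field sizes/positions")
  common <- sort(common)
  at <- vapply(kv, function(e) e$value[match(common, e$key)], numeric(length(common)))
  at <- matrix(at, nrow = length(common))
  pairs <- utils::combn(seq_along(curves), 2)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1, p]; j <- pairs[2, p]
    data.frame(key = common, a = nm[i], b = nm[j],
               diff = at[, i] - at[, j],
               pct_diff = 100 * (at[, i] - at[, j]) / at[, j])
  }))
  spread <- data.frame(key = common,
                       abs_spread = apply(at, 1L, max) - apply(at, 1L, min))
  list(pairwise = pairwise, spread = spread,
       max_spread = spread[which.max(spread$abs_spread), , drop = FALSE])
}
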