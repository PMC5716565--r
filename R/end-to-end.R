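# End-to-end dosimetric verification: film-to-dose conversion, 2D gamma
# analysis, hidden-target offsets, and the isocenter dose report.

#' Planar dose grid
#'
#' @param dose Numeric matrix of doses, cGy, non-negative.
#' @param pitch_mm Grid spacing, mm.
#' @param origin_mm Position `c(x, y)` in mm of the centre of pixel
#'   `[1, 1]`; default centres the grid on (0, 0).
#' @return Object of class `dose_grid`.
#' @export
dose_grid <- function(dose, pitch_mm, origin_mm = NULL) {
  if (!is.matrix(dose) || !is.numeric(dose) || any(!is.finite(dose)) || any(dose < 0))
    linacqa_error("linacqa_validation_error", "dose must be a finite non-negative matrix")
  if (pitch_mm <= 0)
    linacqa_error("linacqa_validation_error", "pitch must be positive")
  if (is.null(origin_mm))
    origin_mm <- -c(ncol(dose) - 1, nrow(dose) - 1) / 2 * pitch_mm
  structure(list(dose = dose, pitch_mm = as.numeric(pitch_mm),
                 origin_mm = as.numeric(origin_mm)),
            class = "dose_grid")
}

#' Write / read a dose grid as headered CSV
#'
#' Three comment header lines carry pitch, origin and units; the body is a
#' plain CSV raster in cGy.
#'
#' @param grid A [dose_grid].
#' @param path File path.
#' @return `write_dose_grid`: `path` invisibly; `read_dose_grid`: a
#'   [dose_grid].
#' @export
write_dose_grid <- function(grid, path) {
  stopifnot(inherits(grid, "dose_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# pitch_mm %.17g", grid$pitch_mm),
               sprintf("# origin_mm %.17g %.17g", grid$origin_mm[1], grid$origin_mm[2]),
               "# units cGy"), con)
  utils::write.table(format_full(grid$dose), con, sep = ",",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dose_grid
#' @export
read_dose_grid <- function(path) {
  raw <- readLines(path, warn = FALSE)
  if (length(raw) < 4L || !grepl("^# pitch_mm ", raw[1]) || !grepl("^# origin_mm ", raw[2]))
    linacqa_error("linacqa_format_error", sprintf("not a dose-grid CSV: %s", path))
  pitch <- as.numeric(sub("^# pitch_mm ", "", raw[1]))
  origin <- as.numeric(strsplit(sub("^# origin_mm ", "", raw[2]), " ")[[1]])
  rows <- strsplit(raw[-(1:3)], ",", fixed = TRUE)
  vals <- suppressWarnings(as.numeric(unlist(rows)))
  if (any(is.na(vals)))
    linacqa_error("linacqa_format_error", "non-numeric cell in dose-grid CSV")
  dose_grid(matrix(vals, ncol = length(rows[[1]]), byrow = TRUE), pitch, origin)
}

#' Convert a scanned film image to dose
#'
#' Applies a per-channel monotone pixel-to-dose calibration curve by linear
#' interpolation and averages the requested channels. Pixels outside the
#' calibration domain are clamped to the curve ends and counted in the
#' `n_clamped` attribute.
#'
#' @param scan A [planar_image] (one channel) or named list of
#'   [planar_image]s (e.g. `red`, `green`) with identical geometry.
#' @param calibration data.frame `(pixel, dose)` applied to every channel,
#'   or a named list of such data.frames per channel. `pixel` must be
#'   strictly monotone.
#' @param channels Channels to convert and average (default all supplied).
#' @return A [dose_grid] at the scan's isocenter-plane pitch, with
#'   attribute `n_clamped`.
#' @export
film_to_dose <- function(scan, calibration, channels = NULL) {
  if (inherits(scan, "planar_image")) scan <- list(gray = scan)
  if (is.null(channels)) channels <- names(scan)
  missing_ch <- setdiff(channels, names(scan))
  if (length(missing_ch))
    linacqa_error("linacqa_validation_error",
                  sprintf("scan lacks channel(s): %s", paste(missing_ch, collapse = ", ")))
  get_cal <- function(ch) {
    cal <- if (is.data.frame(calibration)) calibration else calibration[[ch]]
    if (is.null(cal) || !all(c("pixel", "dose") %in% names(cal)))
      linacqa_error("linacqa_validation_error",
                    sprintf("no (pixel, dose) calibration for channel '%s'", ch))
    d <- diff(cal$pixel)
    if (!(all(d > 0) || all(d < 0)))
      linacqa_error("linacqa_validation_error",
                    sprintf("calibration for channel '%s' is not strictly monotone", ch))
    if (all(d < 0)) cal <- cal[rev(seq_len(nrow(cal))), ]
    cal
  }
  n_clamped <- 0L
  planes <- lapply(channels, function(ch) {
    img <- scan[[ch]]
    cal <- get_cal(ch)
    px <- img$pixels
    n_clamped <<- n_clamped + sum(px < min(cal$pixel) | px > max(cal$pixel))
    matrix(stats::approx(cal$pixel, cal$dose, xout = as.numeric(px), rule = 2)$y,
           nrow(px), ncol(px))
  })
  avg <- Reduce(`+`, planes) / length(planes)
  out <- dose_grid(pmax(avg, 0), iso_pitch(scan[[channels[1]]]))
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Gamma-analysis criteria
#'
#' @param dose_diff_pct Dose-difference criterion, percent (default 3).
#' @param dta_mm Distance-to-agreement criterion, mm (default 1).
#' @param normalization `"global_max"` (percent of the reference maximum)
#'   or `"local"` (percent of the local reference dose).
#' @param low_dose_cutoff_pct Pixels below this percent of the reference
#'   maximum are excluded from the pass rate (default 10).
#' @return Object of class `gamma_criteria`.
#' @export
gamma_criteria <- function(dose_diff_pct = 3, dta_mm = 1,
                           normalization = c("global_max", "local"),
                           low_dose_cutoff_pct = 10) {
  normalization <- match.arg(normalization)
  if (dose_diff_pct <= 0 || dta_mm <= 0)
    linacqa_error("linacqa_validation_error", "both gamma criteria must be positive")
  structure(list(dose_diff_pct = dose_diff_pct, dta_mm = dta_mm,
                 normalization = normalization,
                 low_dose_cutoff_pct = low_dose_cutoff_pct),
            class = "gamma_criteria")
}

# Bilinear sample of M at constant fractional pixel shift (dr, dc);
# positions falling outside the grid give NA.
shift_bilinear <- function(M, dr, dc) {
  fr <- floor(dr); fc <- floor(dc)
  wr <- dr - fr; wc <- dc - fc
  grab <- function(ar, ac) {
    out <- matrix(NA_real_, nrow(M), ncol(M))
    rs <- seq_len(nrow(M)) + ar; cs <- seq_len(ncol(M)) + ac
    rok <- rs >= 1L & rs <= nrow(M); cok <- cs >= 1L & cs <= ncol(M)
    out[rok, cok] <- M[rs[rok], cs[cok]]
    out
  }
  # a corner with zero weight must not contribute (0 * NA is NA in R), so
  # integer shifts stay valid up to the grid edge
  term <- function(w, ar, ac) if (w == 0) 0 else w * grab(ar, ac)
  term((1 - wr) * (1 - wc), fr, fc) +
    term((1 - wr) * wc, fr, fc + 1) +
    term(wr * (1 - wc), fr + 1, fc) +
    term(wr * wc, fr + 1, fc + 1)
}

#' 2D gamma index map
#'
#' Per-pixel gamma of an evaluated dose grid against a reference:
#' the minimum over a search disc (radius `3 * dta`) of
#' `sqrt((dose difference / DD)^2 + (distance / DTA)^2)`, with the
#' evaluated grid sampled by bilinear interpolation on a `dta / 10` sub-pixel
#' step. Both grids must be co-registered with equal pitch.
#'
#' @param ref,eval_ [dose_grid]s on identical grids.
#' @param criteria A [gamma_criteria].
#' @param roi Optional logical matrix restricting the pass-rate region
#'   (default: whole grid).
#' @return Object of class `gamma_map`: `gamma` matrix, `pass_rate_pct`
#'   (gamma <= 1 within the ROI above the low-dose cutoff), `evaluated`
#'   logical matrix, `criteria`.
#' @export
gamma_map <- function(ref, eval_, criteria = gamma_criteria(), roi = NULL) {
  stopifnot(inherits(ref, "dose_grid"), inherits(eval_, "dose_grid"))
  if (abs(ref$pitch_mm - eval_$pitch_mm) > 1e-9)
    linacqa_error("linacqa_validation_error", "reference and evaluated pitch differ")
  if (!all(dim(ref$dose) == dim(eval_$dose)))
    linacqa_error("linacqa_validation_error", "reference and evaluated grid sizes differ")
  D <- ref$dose
  dd_abs <- if (criteria$normalization == "global_max")
    matrix(criteria$dose_diff_pct / 100 * max(D), nrow(D), ncol(D))
  else criteria$dose_diff_pct / 100 * pmax(D, 1e-12)
  pitch <- ref$pitch_mm
  dta <- criteria$dta_mm
  step <- dta / 10
  radius <- 3 * dta
  k <- ceiling(radius / step)
  off <- expand.grid(ox = (-k:k) * step, oy = (-k:k) * step)
  off$r2 <- off$ox^2 + off$oy^2
  off <- off[off$r2 <= radius^2, ]
  off <- off[order(off$r2), ]
  g2 <- matrix(Inf, nrow(D), ncol(D))
  for (i in seq_len(nrow(off))) {
    r2term <- off$r2[i] / dta^2
    if (r2term >= max(g2)) break
    ev <- shift_bilinear(eval_$dose, off$oy[i] / pitch, off$ox[i] / pitch)
    cand <- ((ev - D) / dd_abs)^2 + r2term
    cand[is.na(cand)] <- Inf
    g2 <- pmin(g2, cand)
  }
  gamma <- sqrt(g2)
  if (is.null(roi)) roi <- matrix(TRUE, nrow(D), ncol(D))
  evaluated <- roi & (D >= criteria$low_dose_cutoff_pct / 100 * max(D)) & is.finite(gamma)
  structure(list(gamma = gamma,
                 pass_rate_pct = 100 * mean(gamma[evaluated] <= 1),
                 evaluated = evaluated,
                 criteria = criteria),
            class = "gamma_map")
}

#' Hidden-target test: per-image offsets and 3D isocenter estimate
#'
#' Runs the Winston-Lutz detectors on the four cardinal portal images of an
#' embedded BB and combines the offsets into a 3D localization residual.
#'
#' @param images List of four [planar_image]s labelled with gantry 0, 90,
#'   180, 270 at table zero.
#' @return `list(per_image = data.frame(gantry_deg, x, y), isocenter =
#'   c(rl, ap, is_))`, mm.
#' @export
hidden_target_offsets <- function(images) {
  results <- lapply(images, analyze_wl_image)
  df <- do.call(rbind, lapply(results, function(r)
    data.frame(gantry_deg = r$gantry_deg, table_deg = r$table_deg,
               x = unname(r$offset["x"]), y = unname(r$offset["y"]))))
  list(per_image = df, isocenter = isocenter_from_cardinal(df))
}

#' Isocenter dose comparison report
#'
#' Per-beam and total percent differences of measured versus planned
#' isocenter dose. Displayed values are rounded to one decimal; unrounded
#' values are retained. The total percent difference is computed from the
#' dose sums, not as the mean of the per-beam percentages.
#'
#' @param planned_cgy,measured_cgy Equal-length positive dose vectors, cGy.
#' @return Object of class `dose_comparison_report`: `per_beam` data.frame
#'   (`beam`, `planned_cgy`, `measured_cgy`, `pct_diff`, `pct_diff_display`),
#'   `total_planned_cgy`, `total_measured_cgy`, `total_pct_diff`,
#'   `total_pct_diff_display`.
#' @export
isocenter_dose_report <- function(planned_cgy, measured_cgy) {
  if (length(planned_cgy) != length(measured_cgy) || length(planned_cgy) < 1L)
    linacqa_error("linacqa_validation_error", "planned and measured must be equal-length, non-empty")
  if (any(planned_cgy <= 0))
    linacqa_error("linacqa_validation_error", "planned doses must be positive")
  pct <- 100 * (measured_cgy - planned_cgy) / planned_cgy
  tp <- sum(planned_cgy); tm <- sum(measured_cgy)
  tpct <- 100 * (tm - tp) / tp
  structure(list(
    per_beam = data.frame(beam = seq_along(planned_cgy),
                          planned_cgy = planned_cgy, measured_cgy = measured_cgy,
                          pct_diff = pct, pct_diff_display = round(pct, 1)),
    total_planned_cgy = tp, total_measured_cgy = tm,
    total_pct_diff = tpct, total_pct_diff_display = round(tpct, 1)),
    class = "dose_comparison_report")
}

#' @export
print.dose_comparison_report <- function(x, ...) {
  tab <- x$per_beam
  cat("Isocenter dose comparison\n")
  cat(sprintf("  beam %d: plan %.1f cGy, measured %.1f cGy, diff %+.1f%%\n",
              tab$beam, tab$planned_cgy, tab$measured_cgy, tab$pct_diff_display), sep = "")
  cat(sprintf("  total: plan %.1f cGy, measured %.1f cGy, diff %+.1f%%\n",
              x$total_planned_cgy, x$total_measured_cgy, x$total_pct_diff_display))
  invisible(x)
}
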