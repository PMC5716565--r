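# Relative MTF from line-pair phantom images and the 50% frequency summary.

#' Compute a relative MTF curve from line-pair ROIs
#'
#' For each frequency group the ROI is averaged across rows into a 1D
#' profile; the modulation is `M = (P_high - P_low)/(P_high + P_low)` with
#' `P_high`/`P_low` the medians of the profile's local peak and trough
#' values. The curve is normalized to the modulation at `norm_frequency`,
#' so it is invariant to affine intensity transforms of the image. Groups
#' without detectable bars are flagged absent and dropped from the curve.
#'
#' @param image A [planar_image] of the line-pair phantom.
#' @param group_rois List of `list(rows = c(r0, r1), cols = c(c0, c1),
#'   frequency_lp_mm =)` entries (1-based inclusive pixel ranges), each
#'   containing at least two full bar periods.
#' @param norm_frequency Normalization frequency, lp/mm (default 0.5).
#' @return Object of class `mtf_curve`: data.frame
#'   `(frequency_lp_mm, rmtf)` sorted by frequency, with attributes
#'   `norm_frequency` and `absent_groups`.
#' @export
compute_rmtf <- function(image, group_rois, norm_frequency = 0.5) {
  stopifnot(inherits(image, "planar_image"))
  freqs <- vapply(group_rois, `[[`, numeric(1), "frequency_lp_mm")
  if (!any(abs(freqs - norm_frequency) < 1e-9))
    linacqa_error("linacqa_validation_error",
                  sprintf("normalization frequency %g lp/mm has no ROI", norm_frequency))
  modulation <- function(roi) {
    sub <- image$pixels[roi$rows[1]:roi$rows[2], roi$cols[1]:roi$cols[2], drop = FALSE]
    v <- colMeans(sub)
    n <- length(v)
    if (n < 3L) return(NA_real_)
    i <- 2:(n - 1L)
    peaks <- v[i][v[i] > v[i - 1L] & v[i] >= v[i + 1L]]
    troughs <- v[i][v[i] < v[i - 1L] & v[i] <= v[i + 1L]]
    if (length(peaks) < 1L || length(troughs) < 1L) return(NA_real_)
    ph <- stats::median(peaks); pl <- stats::median(troughs)
    if (ph + pl <= 0 || ph <= pl) return(NA_real_)
    (ph - pl) / (ph + pl)
  }
  m <- vapply(group_rois, modulation, numeric(1))
  m_norm <- m[which(abs(freqs - norm_frequency) < 1e-9)[1]]
  if (is.na(m_norm) || m_norm <= 0)
    linacqa_error("linacqa_validation_error",
                  "no detectable bars in the normalization-frequency ROI")
  absent <- freqs[is.na(m)]
  keep <- !is.na(m)
  ord <- order(freqs[keep])
  structure(data.frame(frequency_lp_mm = freqs[keep][ord],
                       rmtf = (m[keep] / m_norm)[ord]),
            norm_frequency = norm_frequency,
            absent_groups = absent,
            class = c("mtf_curve", "data.frame"))
}

#' Frequency at 50% relative MTF
#'
#' Linear interpolation of the first downward crossing of 0.5 on the RMTF
#' curve.
#'
#' @param curve An [compute_rmtf()] result (or data.frame with
#'   `frequency_lp_mm`, `rmtf`).
#' @return f50 in lp/mm.
#' @export
f50 <- function(curve) {
  f <- curve$frequency_lp_mm; r <- curve$rmtf
  if (length(f) < 2L)
    linacqa_error("linacqa_range_error", "curve too short to locate the 50% crossing")
  for (i in seq_len(length(f) - 1L)) {
    if (r[i] >= 0.5 && r[i + 1L] < 0.5)
      return(f[i] + (0.5 - r[i]) / (r[i + 1L] - r[i]) * (f[i + 1L] - f[i]))
  }
  linacqa_error("linacqa_range_error", "RMTF curve does not cross 0.5")
}
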