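# Winston-Lutz analysis: sub-pixel BB and radiation-field centre detection
# on portal images, and combination of the four cardinal gantry-angle
# offsets into a 3D isocenter estimate.

# Otsu's threshold on a 256-bin histogram; returns the split value.
otsu_threshold <- function(v) {
  rng <- range(v)
  if (diff(rng) <= 0) return(rng[1])
  h <- tabulate(pmin(255L, as.integer((v - rng[1]) / diff(rng) * 256)) + 1L, 256L)
  w <- cumsum(as.numeric(h)); m <- cumsum(as.numeric(h) * seq_len(256L))
  tot_w <- w[256L]; tot_m <- m[256L]
  between <- (tot_m * w - m * tot_w)^2 / (w * (tot_w - w))
  between[!is.finite(between)] <- -Inf
  k <- which.max(between)
  rng[1] + k / 256 * diff(rng)
}

# Plateau/baseline as robust medians of the top decile inside and bottom
# decile outside a coarse Otsu split; the BB dip sits well below the top
# decile, so it does not bias the plateau.
field_levels <- function(px) {
  thr <- otsu_threshold(px)
  inside <- px[px > thr]; outside <- px[px <= thr]
  if (length(inside) < 4L || length(outside) < 4L ||
      diff(range(px)) < 1e-6 * max(abs(px), 1))
    linacqa_error("linacqa_detection_error", "no detectable field (image is uniform)")
  plateau <- stats::median(inside[inside >= stats::quantile(inside, 0.9)])
  baseline <- stats::median(outside[outside <= stats::quantile(outside, 0.1)])
  list(threshold = thr, plateau = plateau, baseline = baseline)
}

# Outermost sub-pixel crossings of `level` in profile `v` sampled at `pos`.
# Scans inward from each end; linear interpolation between samples.
outer_crossings <- function(pos, v, level) {
  above <- v >= level
  if (!any(above) || all(above)) return(NULL)
  li <- which(!above[-length(v)] & above[-1])     # rising edges
  ri <- which(above[-length(v)] & !above[-1])     # falling edges
  if (!length(li) || !length(ri)) return(NULL)
  i <- li[1]; j <- ri[length(ri)]
  left <- pos[i] + (level - v[i]) / (v[i + 1] - v[i]) * (pos[i + 1] - pos[i])
  right <- pos[j] + (level - v[j]) / (v[j + 1] - v[j]) * (pos[j + 1] - pos[j])
  c(left, right)
}

#' Detect the radiation field centre on a portal image
#'
#' Field edges are located at 50% of the in-field plateau minus the exterior
#' baseline (robust decile medians around an Otsu split), with sub-pixel
#' linear interpolation along mean line profiles through the field centre.
#' The centre is the midpoint of the crossings on each axis, refined once.
#' Works for rectangular MLC apertures and circular cones alike.
#'
#' @param image A [planar_image] containing a single high-intensity field.
#' @return `list(center, edges_x_mm, edges_y_mm, plateau, baseline)`;
#'   `center` is a [point2d] in isocenter-plane mm.
#' @export
detect_field_center <- function(image) {
  stopifnot(inherits(image, "planar_image"))
  px <- image$pixels
  cc <- iso_coords(image)
  lv <- field_levels(px)
  half <- (lv$plateau + lv$baseline) / 2
  # rough centre from the above-threshold mask
  mask <- px > lv$threshold
  cx <- sum(colSums(mask) * cc$x) / sum(mask)
  cy <- sum(rowSums(mask) * cc$y) / sum(mask)
  band_mm <- 1
  ex <- ey <- NULL
  for (iter in 1:2) {
    rows <- which(abs(cc$y - cy) <= band_mm)
    cols <- which(abs(cc$x - cx) <= band_mm)
    if (!length(rows) || !length(cols))
      linacqa_error("linacqa_detection_error", "field centre fell outside the raster")
    prof_x <- colMeans(px[rows, , drop = FALSE])
    prof_y <- rowMeans(px[, cols, drop = FALSE])
    ex <- outer_crossings(cc$x, prof_x, half)
    ey <- outer_crossings(cc$y, prof_y, half)
    if (is.null(ex) || is.null(ey))
      linacqa_error("linacqa_detection_error", "no 50% edge crossing found")
    cx <- mean(ex); cy <- mean(ey)
  }
  list(center = point2d(cx, cy), edges_x_mm = ex, edges_y_mm = ey,
       plateau = lv$plateau, baseline = lv$baseline)
}

# 4-connected component labelling on a logical matrix (flood fill).
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    nr <- nrow(mask)
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      r <- (p - 1L) %% nr + 1L; c0 <- (p - 1L) %/% nr + 1L
      for (q in c(if (r > 1L) p - 1L, if (r < nr) p + 1L,
                  if (c0 > 1L) p - nr, if (c0 < ncol(mask)) p + nr)) {
        if (mask[q] && lab[q] == 0L) { lab[q] <- nxt; queue <- c(queue, q) }
      }
    }
  }
  lab
}

#' Detect the BB centre on a Winston-Lutz portal image
#'
#' Segments the dark ball inside the field by thresholding at half the dip
#' depth below the field plateau, then takes the intensity-weighted centroid
#' with weight `(threshold - intensity)+`, giving sub-pixel accuracy.
#'
#' @param image A [planar_image] with a single 2-6 mm dark disc inside the
#'   field.
#' @param margin_mm Interior margin kept clear of the field edge when
#'   searching for the BB (default 1.5 mm).
#' @return BB centre as a [point2d], isocenter-plane mm.
#' @export
detect_bb_center <- function(image, margin_mm = 1.5) {
  stopifnot(inherits(image, "planar_image"))
  px <- image$pixels
  cc <- iso_coords(image)
  fc <- detect_field_center(image)
  half_x <- diff(fc$edges_x_mm) / 2
  half_y <- diff(fc$edges_y_mm) / 2
  r_int <- min(half_x, half_y) - margin_mm
  if (r_int <= 0)
    linacqa_error("linacqa_detection_error", "field too small to search for a BB")
  R2 <- outer((cc$y - fc$center["y"])^2, (cc$x - fc$center["x"])^2, `+`)
  interior <- R2 < r_int^2
  vals <- px[interior]
  dip <- fc$plateau - min(vals)
  if (dip < 0.2 * (fc$plateau - fc$baseline))
    linacqa_error("linacqa_detection_error", "no BB dip detected inside the field")
  thr <- fc$plateau - dip / 2
  cand <- interior & px < thr
  lab <- label_components(cand)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= 4L)
  if (length(keep) == 0L)
    linacqa_error("linacqa_detection_error", "no BB candidate disc found")
  if (length(keep) > 1L)
    linacqa_error("linacqa_detection_error",
                  sprintf("%d candidate discs found; expected exactly one", length(keep)))
  sel <- lab == keep
  w <- pmax(thr - px, 0) * sel
  X <- matrix(cc$x, nrow(px), ncol(px), byrow = TRUE)
  Y <- matrix(cc$y, nrow(px), ncol(px))
  point2d(sum(w * X) / sum(w), sum(w * Y) / sum(w))
}

#' Analyze one Winston-Lutz image
#'
#' Runs field and BB detection and reports the BB-minus-field-centre offset
#' in isocenter-plane mm.
#'
#' @param image A [planar_image]; its `gantry_deg`/`table_deg` labels are
#'   carried into the result.
#' @return Object of class `wl_image_result`: `bb_center`, `field_center`,
#'   `offset` (bb - field), `gantry_deg`, `table_deg`.
#' @export
analyze_wl_image <- function(image) {
  fc <- detect_field_center(image)
  bb <- detect_bb_center(image)
  structure(list(bb_center = bb, field_center = fc$center,
                 offset = point2d(bb["x"] - fc$center["x"], bb["y"] - fc$center["y"]),
                 gantry_deg = image$gantry_deg, table_deg = image$table_deg),
            class = "wl_image_result")
}

#' Combine cardinal-angle offsets into a 3D isocenter offset
#'
#' From BB offsets measured at gantry 0/90/180/270 with the table at zero,
#' the BB location relative to the radiation isocenter is
#' `rl = (G0.x - G180.x)/2` (R-/L+), `ap = (G90.x - G270.x)/2` (A-/P+) and
#' `is = (G0.y + G90.y + G180.y + G270.y)/4` (I-/S+).
#'
#' @param offsets data.frame with columns `gantry_deg`, `x`, `y` (mm at the
#'   isocenter plane) and optionally `table_deg`; must contain exactly the
#'   four cardinal gantry angles, each once, at table zero.
#' @return Named numeric `c(rl =, ap =, is_ =)`, mm.
#' @export
isocenter_from_cardinal <- function(offsets) {
  if (inherits(offsets, "wl_image_result")) offsets <- list(offsets)
  if (is.list(offsets) && !is.data.frame(offsets) &&
      all(vapply(offsets, inherits, logical(1), "wl_image_result"))) {
    offsets <- do.call(rbind, lapply(offsets, function(r)
      data.frame(gantry_deg = r$gantry_deg, table_deg = r$table_deg,
                 x = r$offset["x"], y = r$offset["y"])))
  }
  need <- c(0, 90, 180, 270)
  if (!is.data.frame(offsets) || !all(c("gantry_deg", "x", "y") %in% names(offsets)))
    linacqa_error("linacqa_validation_error",
                  "offsets must be a data.frame with gantry_deg, x, y")
  if ("table_deg" %in% names(offsets) && any(offsets$table_deg != 0))
    linacqa_error("linacqa_validation_error",
                  "isocenter combination requires table-zero images only")
  if (!setequal(offsets$gantry_deg, need) || nrow(offsets) != 4L)
    linacqa_error("linacqa_validation_error",
                  "need exactly one offset for each of gantry 0, 90, 180, 270")
  g <- function(a, comp) offsets[[comp]][offsets$gantry_deg == a]
  c(rl = (g(0, "x") - g(180, "x")) / 2,
    ap = (g(90, "x") - g(270, "x")) / 2,
    is_ = (g(0, "y") + g(90, "y") + g(180, "y") + g(270, "y")) / 4)
}

#' Summarize a batch of Winston-Lutz results
#'
#' Per-image offset magnitudes with pass/fail against a tolerance (default
#' 1.0 mm, the SRS/SBRT isocentricity tolerance of TG-142).
#'
#' @param results List of `wl_image_result` (or a data.frame with `x`, `y`
#'   offset columns).
#' @param tolerance_mm Pass tolerance on the offset magnitude, mm.
#' @return `list(per_image = data.frame, max_mm, mean_mm, tolerance_mm,
#'   pass)`.
#' @export
wl_batch_summary <- function(results, tolerance_mm = 1.0) {
  if (inherits(results, "wl_image_result")) results <- list(results)
  if (is.data.frame(results)) {
    df <- results
    if (!all(c("x", "y") %in% names(df)))
      linacqa_error("linacqa_validation_error", "offset data.frame needs x and y")
    if (is.null(df$gantry_deg)) df$gantry_deg <- NA_real_
    if (is.null(df$table_deg)) df$table_deg <- NA_real_
  } else {
    if (length(results) == 0L)
      linacqa_error("linacqa_validation_error", "no results to summarize")
    df <- do.call(rbind, lapply(results, function(r)
      data.frame(gantry_deg = r$gantry_deg, table_deg = r$table_deg,
                 x = unname(r$offset["x"]), y = unname(r$offset["y"]))))
  }
  df$magnitude_mm <- sqrt(df$x^2 + df$y^2)
  df$pass <- df$magnitude_mm <= tolerance_mm
  list(per_image = df,
       max_mm = max(df$magnitude_mm),
       mean_mm = mean(df$magnitude_mm),
       tolerance_mm = tolerance_mm,
       pass = all(df$pass))
}
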