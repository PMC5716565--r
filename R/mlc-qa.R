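# MLC quality-assurance analyses: picket fence, star shot, leaf
# transmission, and the dynamic leaf gap (sweeping gap) fit.

#' Sweeping-gap dose series
#'
#' Nominal-gap versus measured-dose pairs for the dynamic-leaf-gap test,
#' together with the separately measured leakage dose.
#'
#' @param gaps_mm Strictly increasing nominal gaps, mm.
#' @param doses_gy Measured doses, Gy; each must exceed `dleak_gy`.
#' @param dleak_gy Leakage dose (all leaves closed, gap offset off-axis), Gy.
#' @return Object of class `sweeping_gap_series`.
#' @export
sweeping_gap_series <- function(gaps_mm, doses_gy, dleak_gy) {
  if (length(gaps_mm) != length(doses_gy) || length(gaps_mm) < 2L)
    linacqa_error("linacqa_validation_error", "need >= 2 (gap, dose) pairs of equal length")
  if (any(diff(gaps_mm) <= 0))
    linacqa_error("linacqa_validation_error", "gaps must be strictly increasing")
  if (any(doses_gy <= dleak_gy))
    linacqa_error("linacqa_validation_error", "all doses must exceed the leakage dose")
  structure(list(gaps_mm = as.numeric(gaps_mm), doses_gy = as.numeric(doses_gy),
                 dleak_gy = as.numeric(dleak_gy)),
            class = "sweeping_gap_series")
}

#' Fit the dynamic leaf gap from a sweeping-gap series
#'
#' Ordinary least squares of the leakage-subtracted dose on the nominal gap:
#' `D - Dleak = b * (gap + 2 * delta)`. The fitted line's root on the gap
#' axis is the zero-dose gap; the dynamic leaf shift is the negative half of
#' that intercept.
#'
#' @param series A [sweeping_gap_series].
#' @return `list(slope_b_gy_mm, x_intercept_mm, delta_mm, residual_rms_gy)`.
#' @export
fit_dynamic_leaf_gap <- function(series) {
  stopifnot(inherits(series, "sweeping_gap_series"))
  y <- series$doses_gy - series$dleak_gy
  fit <- stats::lm(y ~ gaps, data = list(y = y, gaps = series$gaps_mm))
  a <- unname(stats::coef(fit)[1]); b <- unname(stats::coef(fit)[2])
  if (!is.finite(b) || b <= 0)
    linacqa_error("linacqa_fit_error", "sweeping-gap fit has non-positive slope")
  x_int <- -a / b
  list(slope_b_gy_mm = b,
       x_intercept_mm = x_int,
       delta_mm = -x_int / 2,
       residual_rms_gy = sqrt(mean(stats::residuals(fit)^2)))
}

#' MLC transmission
#'
#' Ratio of the dose with the MLC closed to the dose of an MLC-defined open
#' field, as a percentage, flagged against the mean-transmission acceptance
#' limit (default 2%).
#'
#' @param dose_closed,dose_open Measured doses (any common unit).
#' @param tolerance_pct Acceptance limit in percent.
#' @return `list(transmission_pct, tolerance_pct, pass)`.
#' @export
mlc_transmission <- function(dose_closed, dose_open, tolerance_pct = 2) {
  if (!is.numeric(dose_open) || dose_open <= 0)
    linacqa_error("linacqa_validation_error", "open-field dose must be positive")
  if (dose_closed < 0)
    linacqa_error("linacqa_validation_error", "closed-MLC dose must be non-negative")
  pct <- 100 * dose_closed / dose_open
  list(transmission_pct = pct, tolerance_pct = tolerance_pct,
       pass = pct < tolerance_pct)
}

#' Analyze a picket-fence image
#'
#' Averages the raster across the direction orthogonal to leaf travel,
#' detects the bright bands, and reports each picket's sub-pixel position
#' (centroid of the band above half-prominence), FWHM, inter-picket
#' distances, and the maximum deviation from a best-fit equispaced grid at
#' the nominal spacing (free phase, median-anchored).
#'
#' @param image A [planar_image] with >= 2 roughly vertical pickets.
#' @param nominal_spacing_mm Nominal interline distance at the isocenter.
#' @return Object of class `picket_fence_result`: `positions_mm`,
#'   `distances_mm`, `fwhm_mm`, `deviations_mm`, `max_deviation_mm`.
#' @export
analyze_picket_fence <- function(image, nominal_spacing_mm = 30) {
  stopifnot(inherits(image, "planar_image"))
  cc <- iso_coords(image)
  prof <- colMeans(image$pixels)
  baseline <- stats::quantile(prof, 0.25, names = FALSE)
  top <- max(prof)
  if (top - baseline <= 1e-9)
    linacqa_error("linacqa_detection_error", "no pickets detected (flat profile)")
  level <- baseline + 0.5 * (top - baseline)
  above <- prof >= level
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  bands <- cbind(starts, ends)[runs$values, , drop = FALSE]
  if (nrow(bands) < 2L)
    linacqa_error("linacqa_detection_error",
                  sprintf("only %d picket band(s) detected; need >= 2", nrow(bands)))
  pos <- fw <- numeric(nrow(bands))
  for (k in seq_len(nrow(bands))) {
    i0 <- bands[k, 1]; i1 <- bands[k, 2]
    peak <- max(prof[i0:i1])
    half <- baseline + 0.5 * (peak - baseline)
    # sub-pixel half-prominence crossings just outside the band
    li <- max(i0 - 1L, 1L); ri <- min(i1 + 1L, length(prof))
    xl <- if (prof[li] < half && li < i0)
      cc$x[li] + (half - prof[li]) / (prof[i0] - prof[li]) * (cc$x[i0] - cc$x[li])
    else cc$x[i0]
    xr <- if (prof[ri] < half && ri > i1)
      cc$x[i1] + (half - prof[i1]) / (prof[ri] - prof[i1]) * (cc$x[ri] - cc$x[i1])
    else cc$x[i1]
    fw[k] <- xr - xl
    # centroid weighted by height above the half level: the weight vanishes
    # at the band boundary, so pixel in/exclusion at the edges cannot bias
    # the sub-pixel position
    sel <- i0:i1
    w <- pmax(prof[sel] - half, 0)
    pos[k] <- sum(w * cc$x[sel]) / sum(w)
  }
  idx <- seq_along(pos)
  phase <- stats::median(pos - idx * nominal_spacing_mm)
  dev <- pos - (idx * nominal_spacing_mm + phase)
  structure(list(positions_mm = pos,
                 distances_mm = diff(pos),
                 fwhm_mm = fw,
                 nominal_spacing_mm = nominal_spacing_mm,
                 deviations_mm = dev,
                 max_deviation_mm = max(abs(dev))),
            class = "picket_fence_result")
}

#' Exact minimum enclosing circle
#'
#' Smallest circle covering a set of 2D points, found by the exact
#' two-point (diameter) and three-point (circumcircle) candidate search.
#'
#' @param pts Two-column matrix of points (x, y).
#' @return `list(center = c(x, y), radius)`.
#' @export
min_enclosing_circle <- function(pts) {
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  if (n == 0L) linacqa_error("linacqa_validation_error", "no points")
  if (n == 1L) return(list(center = as.numeric(pts[1, ]), radius = 0))
  covers <- function(c0, r) all(sqrt((pts[, 1] - c0[1])^2 + (pts[, 2] - c0[2])^2) <= r + 1e-9)
  best <- list(center = NULL, radius = Inf)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    c0 <- (pts[i, ] + pts[j, ]) / 2
    r <- sqrt(sum((pts[i, ] - pts[j, ])^2)) / 2
    if (r < best$radius && covers(c0, r)) best <- list(center = as.numeric(c0), radius = r)
  }
  if (n >= 3L) {
    for (i in seq_len(n - 2L)) for (j in (i + 1L):(n - 1L)) for (k in (j + 1L):n) {
      cc <- circumcenter(pts[i, ], pts[j, ], pts[k, ])
      if (is.null(cc)) next
      r <- sqrt(sum((pts[i, ] - cc)^2))
      if (r < best$radius && covers(cc, r)) best <- list(center = as.numeric(cc), radius = r)
    }
  }
  best
}

circumcenter <- function(a, b, c) {
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
  if (abs(d) < 1e-12) return(NULL)
  ux <- (sum(a^2) * (b[2] - c[2]) + sum(b^2) * (c[2] - a[2]) + sum(c^2) * (a[2] - b[2])) / d
  uy <- (sum(a^2) * (c[1] - b[1]) + sum(b^2) * (a[1] - c[1]) + sum(c^2) * (b[1] - a[1])) / d
  c(ux, uy)
}

#' Analyze a star-shot (spoke-shot) image
#'
#' Dark slit pixels are clustered by angle about their centroid (0.5-degree
#' bins), each spoke is fitted by darkness-weighted total least squares, all
#' pairwise line intersections are computed, and the minimum enclosing
#' circle of the intersections is reported. The spokes should intersect
#' within a 1 mm radius circle.
#'
#' @param image A [planar_image] with >= 2 non-parallel slit lines.
#' @param tolerance_mm Pass tolerance on the circle radius (default 1 mm).
#' @return Object of class `star_shot_result`: `lines` (data.frame with
#'   angle and a point on each line), `intersections` (matrix),
#'   `circle` (`list(center, radius)`), `pass`.
#' @export
analyze_star_shot <- function(image, tolerance_mm = 1) {
  stopifnot(inherits(image, "planar_image"))
  px <- image$pixels
  cc <- iso_coords(image)
  bg <- stats::median(px)
  depth <- bg - min(px)
  if (depth < 0.2 * max(bg, 1e-12))
    linacqa_error("linacqa_detection_error", "no slit lines detected")
  level <- bg - 0.5 * depth
  mask <- px < level
  X <- matrix(cc$x, nrow(px), ncol(px), byrow = TRUE)
  Y <- matrix(cc$y, nrow(px), ncol(px))
  # weight vanishes at the mask boundary so pixel in/exclusion at the slit
  # edges cannot bias the fits
  w_all <- pmax(level - px, 0)
  cx <- sum(w_all[mask] * X[mask]) / sum(w_all[mask])
  cy <- sum(w_all[mask] * Y[mask]) / sum(w_all[mask])
  r <- sqrt((X[mask] - cx)^2 + (Y[mask] - cy)^2)
  keep <- r > 5            # drop the overlap blob near the hub
  xs <- X[mask][keep]; ys <- Y[mask][keep]; ws <- w_all[mask][keep]
  if (length(xs) < 10L)
    linacqa_error("linacqa_detection_error", "too few slit pixels for line fitting")
  ang <- (atan2(ys - cy, xs - cx) * 180 / pi) %% 180
  bin <- floor(ang / 0.5)
  nbin <- 360L
  counts <- tabulate(bin + 1L, nbin)
  # ignore sparsely hit bins (tails where slits overlap near the hub)
  occ <- counts >= max(2, 0.1 * max(counts))
  idx <- which(occ)
  # group occupied bins, tolerating gaps of up to 2 bins, circular at the
  # 0/180 wrap
  lab <- cumsum(c(TRUE, diff(idx) > 3L))
  groups <- split(idx - 1L, lab)
  if (length(groups) > 1L && idx[1L] <= 3L && idx[length(idx)] >= nbin - 3L) {
    groups[[1L]] <- c(groups[[length(groups)]], groups[[1L]])
    groups[[length(groups)]] <- NULL
  }
  groups <- Filter(function(b) sum(counts[b + 1L]) >= 30L, groups)
  if (length(groups) == 0L)
    linacqa_error("linacqa_detection_error", "no slit-line clusters found")
  fit_line <- function(sel) {
    m <- c(sum(ws[sel] * xs[sel]), sum(ws[sel] * ys[sel])) / sum(ws[sel])
    dx <- xs[sel] - m[1]; dy <- ys[sel] - m[2]
    cov <- matrix(c(sum(ws[sel] * dx * dx), sum(ws[sel] * dx * dy),
                    sum(ws[sel] * dx * dy), sum(ws[sel] * dy * dy)), 2)
    ev <- eigen(cov, symmetric = TRUE)
    d <- ev$vectors[, 1]
    list(point = m, dir = d / sqrt(sum(d^2)),
         angle_deg = (atan2(d[2], d[1]) * 180 / pi) %% 180)
  }
  # fit each angular cluster; split clusters whose perpendicular residuals
  # are bimodal (two separated parallel slits share one angle bin range)
  lines <- list()
  for (bins in groups) {
    sel <- which(bin %in% bins)
    l <- fit_line(sel)
    nrm <- c(-l$dir[2], l$dir[1])
    rho <- (xs[sel] - l$point[1]) * nrm[1] + (ys[sel] - l$point[2]) * nrm[2]
    if (max(rho) - min(rho) > 3) {
      o <- order(rho)
      gaps <- diff(rho[o])
      cut <- which.max(gaps)
      if (gaps[cut] > 1.5) {
        lines[[length(lines) + 1L]] <- fit_line(sel[o[seq_len(cut)]])
        lines[[length(lines) + 1L]] <- fit_line(sel[o[(cut + 1L):length(sel)]])
        next
      }
    }
    lines[[length(lines) + 1L]] <- l
  }
  # refinement: assign every slit pixel to its nearest fitted line (within
  # 2 mm perpendicular distance) and refit, so cluster tails do not bias
  # the total-least-squares solutions
  dmat <- vapply(lines, function(l)
    abs((xs - l$point[1]) * (-l$dir[2]) + (ys - l$point[2]) * l$dir[1]),
    numeric(length(xs)))
  dmat <- matrix(dmat, ncol = length(lines))
  nearest <- max.col(-dmat, ties.method = "first")
  mind <- dmat[cbind(seq_along(xs), nearest)]
  lines <- lapply(seq_along(lines), function(k) {
    sel <- which(nearest == k & mind < 2)
    if (length(sel) >= 10L) fit_line(sel) else lines[[k]]
  })
  # merge duplicate fits of the same physical line
  if (length(lines) > 1L) {
    angs <- vapply(lines, `[[`, numeric(1), "angle_deg")
    dup <- rep(FALSE, length(lines))
    for (i in seq_along(lines)[-1]) for (j in seq_len(i - 1L)) {
      da <- abs(angs[i] - angs[j]); da <- min(da, 180 - da)
      dperp <- abs(sum((lines[[i]]$point - lines[[j]]$point) *
                         c(-lines[[j]]$dir[2], lines[[j]]$dir[1])))
      if (da < 1 && dperp < 0.5) dup[i] <- TRUE
    }
    lines <- lines[!dup]
  }
  if (length(lines) < 2L)
    linacqa_error("linacqa_detection_error", "fewer than two distinct slit lines found")
  inter <- list()
  for (i in seq_along(lines)[-1]) for (j in seq_len(i - 1L)) {
    d1 <- lines[[i]]$dir; d2 <- lines[[j]]$dir
    cr <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(cr) < 1e-6) next
    dp <- lines[[j]]$point - lines[[i]]$point
    t1 <- (dp[1] * d2[2] - dp[2] * d2[1]) / cr
    inter[[length(inter) + 1L]] <- lines[[i]]$point + t1 * d1
  }
  if (length(inter) == 0L)
    linacqa_error("linacqa_geometry_error", "all slit lines are parallel; no intersections")
  ipts <- do.call(rbind, inter)
  circ <- min_enclosing_circle(ipts)
  structure(list(
    lines = data.frame(angle_deg = vapply(lines, `[[`, numeric(1), "angle_deg"),
                       px = vapply(lines, function(l) l$point[1], numeric(1)),
                       py = vapply(lines, function(l) l$point[2], numeric(1))),
    intersections = ipts,
    circle = circ,
    tolerance_mm = tolerance_mm,
    pass = circ$radius <= tolerance_mm),
    class = "star_shot_result")
}
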