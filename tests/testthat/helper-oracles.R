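# Independent oracles used by the unit and acceptance tests. These are
# deliberately written along different routes than the package code paths
# they check.

# Minimum enclosing circle by numerical minimax: Nelder-Mead on
# f(c) = max_i |p_i - c|, restarted from the centroid and the farthest-pair
# midpoint, polished with a tight tolerance.
mec_oracle <- function(pts) {
  pts <- as.matrix(pts)
  f <- function(c0) max(sqrt((pts[, 1] - c0[1])^2 + (pts[, 2] - c0[2])^2))
  starts <- list(colMeans(pts))
  d <- as.matrix(dist(pts))
  ij <- which(d == max(d), arr.ind = TRUE)[1, ]
  starts[[2]] <- (pts[ij[1], ] + pts[ij[2], ]) / 2
  best <- NULL
  for (s in starts) {
    o <- stats::optim(s, f, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
    if (is.null(best) || o$value < best$value) best <- o
  }
  list(center = as.numeric(best$par), radius = best$value)
}

# Per-pixel exhaustive gamma search with an independently written bilinear
# interpolator, over the same candidate offsets (step dta/10, disc radius
# 3*dta) as the package implementation.
gamma_oracle <- function(ref, eval_, criteria) {
  D <- ref$dose; E <- eval_$dose
  pitch <- ref$pitch_mm
  dta <- criteria$dta_mm
  dd_abs <- if (criteria$normalization == "global_max")
    criteria$dose_diff_pct / 100 * max(D)
  else NULL
  step <- dta / 10; radius <- 3 * dta
  k <- ceiling(radius / step)
  off <- expand.grid(ox = (-k:k) * step, oy = (-k:k) * step)
  off <- off[off$ox^2 + off$oy^2 <= radius^2, ]
  r2 <- (off$ox^2 + off$oy^2) / dta^2
  nr <- nrow(D); nc <- ncol(D)
  bil <- function(rr, cc) {
    r0 <- floor(rr); c0 <- floor(cc)
    wr <- rr - r0; wc <- cc - c0
    get <- function(i, j) {
      ok <- i >= 1 & i <= nr & j >= 1 & j <= nc
      out <- rep(NA_real_, length(i))
      out[ok] <- E[cbind(i[ok], j[ok])]
      out
    }
    acc <- rep(0, length(rr)); bad <- rep(FALSE, length(rr))
    for (corner in list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))) {
      w <- (if (corner[1] == 0) 1 - wr else wr) * (if (corner[2] == 0) 1 - wc else wc)
      v <- get(r0 + corner[1], c0 + corner[2])
      use <- w > 0
      bad <- bad | (use & is.na(v))
      acc[use] <- acc[use] + w[use] * v[use]
    }
    acc[bad] <- NA_real_
    acc
  }
  G <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ev <- bil(i + off$oy / pitch, j + off$ox / pitch)
    dd <- if (is.null(dd_abs)) criteria$dose_diff_pct / 100 * max(D[i, j], 1e-12) else dd_abs
    g2 <- ((ev - D[i, j]) / dd)^2 + r2
    G[i, j] <- sqrt(min(g2, na.rm = TRUE))
  }
  G
}

# Two-pass mean/sd oracle (explicit loops, n - 1 denominator).
stats_oracle <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  mu <- numeric(3); s <- numeric(3)
  for (j in 1:3) {
    acc <- 0
    for (i in seq_len(n)) acc <- acc + m[i, j]
    mu[j] <- acc / n
    acc <- 0
    for (i in seq_len(n)) acc <- acc + (m[i, j] - mu[j])^2
    s[j] <- sqrt(acc / (n - 1))
  }
  vl <- sqrt(m[, 1]^2 + m[, 2]^2 + m[, 3]^2)
  list(mean = mu, sd = s, vector_mean = sum(vl) / n,
       vector_sd = sqrt(sum((vl - sum(vl) / n)^2) / (n - 1)))
}

# Disc average of a radial model by 2D Cartesian quadrature (independent of
# the package's 1D radial integration).
disc_average_oracle <- function(model, diameter_mm, field_mm, n = 401) {
  R <- diameter_mm / 2
  u <- seq(-R, R, length.out = n)
  g <- expand.grid(x = u, y = u)
  inside <- g$x^2 + g$y^2 <= R^2
  mean(model(sqrt(g$x[inside]^2 + g$y[inside]^2), field_mm))
}

# Modulation of a blurred square wave by discrete convolution of the bar
# pattern with a Gaussian kernel, evaluated at bar and gap centres.
modulation_oracle <- function(freq_lp_mm, sigma_mm, periods = 4,
                              lo = 0.2, hi = 0.8, dx = 0.002) {
  p <- 1 / freq_lp_mm
  x <- seq(-2, periods * p + 2, by = dx)
  sq <- ifelse((x %% p) < p / 2 & x >= 0 & x <= periods * p, hi, lo)
  kx <- seq(-5 * sigma_mm, 5 * sigma_mm, by = dx)
  kern <- exp(-kx^2 / (2 * sigma_mm^2)); kern <- kern / sum(kern)
  sm <- stats::filter(sq, kern, sides = 2)
  centres <- (seq_len(periods) - 1) * p + p / 4        # bar centres
  gaps <- (seq_len(periods - 1) - 1) * p + 3 * p / 4   # gap centres
  at <- function(x0) sm[which.min(abs(x - x0))]
  ph <- stats::median(vapply(centres, at, numeric(1)))
  pl <- stats::median(vapply(gaps, at, numeric(1)))
  (ph - pl) / (ph + pl)
}

expect_point_near <- function(p, xy, tol) {
  expect_lt(abs(p[["x"]] - xy[1]), tol)
  expect_lt(abs(p[["y"]] - xy[2]), tol)
}
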