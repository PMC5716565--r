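# Image-guidance localization statistics: hidden-target residuals,
# cross-system comparisons, rotation exceedance, and rigid-fit couch
# rotation verification from embedded BBs.

as_residual_matrix <- function(samples) {
  if (is.data.frame(samples)) {
    cols <- intersect(c("dx", "dy", "dz"), names(samples))
    if (length(cols) == 3L) samples <- samples[cols]
    else samples <- samples[, 1:3]
    samples <- as.matrix(samples)
  }
  samples <- as.matrix(samples)
  if (ncol(samples) != 3L)
    linacqa_error("linacqa_validation_error", "residual samples need three columns (x, y, z)")
  storage.mode(samples) <- "double"
  if (any(!is.finite(samples)))
    linacqa_error("linacqa_validation_error", "residual samples must be finite")
  samples
}

#' Residual localization error statistics
#'
#' Per-axis sample mean and standard deviation (n - 1 denominator), and the
#' mean and standard deviation of the per-trial Euclidean vector length.
#'
#' @param samples n x 3 matrix or data.frame (`dx`, `dy`, `dz` in mm on the
#'   L/R, P/A, S/I axes), n >= 2.
#' @return `list(per_axis = data.frame(axis, mean, sd), vector_mean,
#'   vector_sd, n)`.
#' @export
residual_error_stats <- function(samples) {
  m <- as_residual_matrix(samples)
  if (nrow(m) < 2L)
    linacqa_error("linacqa_validation_error", "need at least two samples")
  vec <- sqrt(rowSums(m^2))
  list(per_axis = data.frame(axis = c("x_lr", "y_pa", "z_si"),
                             mean = colMeans(m),
                             sd = apply(m, 2L, stats::sd)),
       vector_mean = mean(vec), vector_sd = stats::sd(vec), n = nrow(m))
}

#' Compare two localization systems on paired shifts
#'
#' Componentwise differences A - B of paired observations, summarized with
#' [residual_error_stats()].
#'
#' @param system_a,system_b Paired n x 3 translation tables (mm).
#' @return As [residual_error_stats()], computed on `A - B`.
#' @export
compare_systems <- function(system_a, system_b) {
  a <- as_residual_matrix(system_a); b <- as_residual_matrix(system_b)
  if (nrow(a) != nrow(b))
    linacqa_error("linacqa_validation_error",
                  sprintf("unpaired observations: %d vs %d rows", nrow(a), nrow(b)))
  residual_error_stats(a - b)
}

#' Rotation exceedance fractions
#'
#' Fraction of registrations whose absolute rotation exceeds each threshold,
#' with the binomial standard error `sqrt(p (1 - p) / n)`.
#'
#' @param angles_deg Observed rotations, degrees.
#' @param thresholds_deg Thresholds, degrees (default 3 and 5).
#' @return data.frame `(threshold_deg, fraction, se, count, n)`.
#' @export
rotation_exceedance <- function(angles_deg, thresholds_deg = c(3, 5)) {
  if (length(angles_deg) < 1L)
    linacqa_error("linacqa_validation_error", "no angles supplied")
  n <- length(angles_deg)
  cnt <- vapply(thresholds_deg, function(t) sum(abs(angles_deg) > t), numeric(1))
  p <- cnt / n
  data.frame(threshold_deg = thresholds_deg, fraction = p,
             se = sqrt(p * (1 - p) / n), count = cnt, n = n)
}

rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)

#' Compose a rotation matrix from 6-DOF rotation angles
#'
#' Convention: `R = Rz(r_si) %*% Ry(r_pa) %*% Rx(r_lr)` with x = L/R,
#' y = P/A, z = S/I and angles in degrees. Below a few degrees the
#' composition order is irrelevant to within ~0.01 degrees.
#'
#' @param r_lr,r_pa,r_si Rotations in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_from_angles <- function(r_lr, r_pa, r_si) {
  d <- pi / 180
  rot_z(r_si * d) %*% rot_y(r_pa * d) %*% rot_x(r_lr * d)
}

#' Rigid transform from corresponding BB positions
#'
#' Least-squares rigid registration (rotation + translation, no scaling) of
#' `points_pre` onto `points_post` by the Kabsch/SVD method, with the
#' rotation decomposed into couch angles about the L/R, P/A and S/I axes
#' (convention of [rotation_from_angles()]).
#'
#' @param points_pre,points_post n x 3 matrices of corresponding points,
#'   n >= 3, not collinear.
#' @return A [sixdof_shift]: translations in mm, rotations in degrees.
#' @export
rigid_from_bbs <- function(points_pre, points_post) {
  p <- as.matrix(points_pre); q <- as.matrix(points_post)
  if (!all(dim(p) == dim(q)) || ncol(p) != 3L || nrow(p) < 3L)
    linacqa_error("linacqa_validation_error", "need matching n x 3 point sets with n >= 3")
  pc <- colMeans(p); qc <- colMeans(q)
  p0 <- sweep(p, 2L, pc); q0 <- sweep(q, 2L, qc)
  sv0 <- svd(p0)
  if (sv0$d[2] < 1e-9 * max(sv0$d[1], 1e-12))
    linacqa_error("linacqa_geometry_error", "degenerate (collinear) point configuration")
  H <- t(p0) %*% q0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- qc - as.numeric(R %*% pc)
  # decompose R = Rz(c) Ry(b) Rx(a)
  b <- asin(max(-1, min(1, -R[3, 1])))
  a <- atan2(R[3, 2], R[3, 3])
  cang <- atan2(R[2, 1], R[1, 1])
  r <- 180 / pi
  sixdof_shift(dx = tr[1], dy = tr[2], dz = tr[3],
               r_lr = a * r, r_pa = b * r, r_si = cang * r)
}

#' Apply a 6-DOF shift to points
#'
#' Forward transform `q = R p + t` with the same rotation convention as
#' [rigid_from_bbs()]; useful as an oracle for round-trip tests.
#'
#' @param points n x 3 matrix.
#' @param shift A [sixdof_shift].
#' @return Transformed n x 3 matrix.
#' @export
apply_sixdof <- function(points, shift) {
  R <- rotation_from_angles(shift["r_lr"], shift["r_pa"], shift["r_si"])
  sweep(as.matrix(points) %*% t(R), 2L, shift[c("dx", "dy", "dz")], `+`)
}
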