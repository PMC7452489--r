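# Rigid-body math: 6-DOF poses, Cardan angles, rigid transforms,
# least-squares frame fitting.
#
# Conventions used throughout the package:
#   * right-handed frames, millimetres, degrees;
#   * Cardan sequence x-y-z about the moving frame's axes, so the rotation
#     matrix is R = Rx(thx) %*% Ry(thy) %*% Rz(thz);
#   * angles reported in (-180, 180]; at gimbal lock (|thy| = 90) thz is
#     fixed to 0 and the remaining rotation folded into thx.

#' Construct a 6-DOF pose
#'
#' A pose holds the position (mm) and orientation (Cardan x-y-z angles,
#' degrees) of a bone's local coordinate system expressed in a world frame
#' (typically the CT frame).
#'
#' @param px,py,pz translation components, mm
#' @param thx,thy,thz Cardan angles about the moving x, y, z axes, degrees
#' @return object of class `pose6`: a named numeric vector of length 6
#' @export
#' @examples
#' pose6(1, 2, 3, 10, 0, -5)
pose6 <- function(px = 0, py = 0, pz = 0, thx = 0, thy = 0, thz = 0) {
  q <- c(px = px, py = py, pz = pz, thx = thx, thy = thy, thz = thz)
  stopifnot_finite(q, "pose")
  q[4:6] <- wrap_angle(q[4:6])
  structure(q, class = "pose6")
}

#' @export
print.pose6 <- function(x, ...) {
  cat(sprintf("pose6: p = (%.3f, %.3f, %.3f) mm, theta = (%.3f, %.3f, %.3f) deg\n",
              x[1], x[2], x[3], x[4], x[5], x[6]))
  invisible(x)
}

as_pose6 <- function(q) {
  q <- as.numeric(q)
  if (length(q) != 6) stop("a pose has exactly 6 components")
  pose6(q[1], q[2], q[3], q[4], q[5], q[6])
}

# Wrap degrees into (-180, 180].
wrap_angle <- function(a) {
  a <- (a + 180) %% 360 - 180
  a[a == -180] <- 180
  a
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

rot_x <- function(deg) {
  c <- cos(deg2rad(deg)); s <- sin(deg2rad(deg))
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}
rot_y <- function(deg) {
  c <- cos(deg2rad(deg)); s <- sin(deg2rad(deg))
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}
rot_z <- function(deg) {
  c <- cos(deg2rad(deg)); s <- sin(deg2rad(deg))
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' Construct a rigid transform
#'
#' @param rotation 3x3 proper orthonormal matrix
#' @param translation length-3 numeric, mm
#' @param tol orthonormality tolerance
#' @return object of class `rigid_transform` with elements `R` and `t`
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            tol = 1e-9) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3, 3)) || length(translation) != 3) {
    stop("rotation must be 3x3 and translation length 3")
  }
  stopifnot_finite(rotation, "rotation")
  stopifnot_finite(translation, "translation")
  if (max(abs(crossprod(rotation) - diag(3))) > tol) {
    stop("rotation is not orthonormal within tolerance")
  }
  if (abs(det(rotation) - 1) > tol) {
    stop("rotation must be proper (det = +1); reflections are not rigid")
  }
  structure(list(R = rotation, t = translation), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform\n  t =", sprintf("%.4f", x$t), "mm\n  R =\n")
  print(round(x$R, 6))
  invisible(x)
}

#' Convert a pose to its rigid transform
#'
#' The rotation is the Cardan x-y-z product `Rx(thx) Ry(thy) Rz(thz)` and the
#' translation is `(px, py, pz)`.
#'
#' @param pose a [pose6()]
#' @return a [rigid_transform()]
#' @export
pose_to_transform <- function(pose) {
  pose <- as_pose6(pose)
  rigid_transform(rot_x(pose[4]) %*% rot_y(pose[5]) %*% rot_z(pose[6]),
                  pose[1:3])
}

#' Recover the pose of a rigid transform
#'
#' Inverse of [pose_to_transform()]. At gimbal lock (`|thy| = 90` degrees)
#' the x/z rotations are indistinguishable; `thz` is set to 0 and the
#' remaining rotation folded into `thx`.
#'
#' @param transform a [rigid_transform()]
#' @return a [pose6()]
#' @export
transform_to_pose <- function(transform) {
  if (!inherits(transform, "rigid_transform")) {
    transform <- rigid_transform(transform$R, transform$t)
  }
  R <- transform$R
  # R = Rx Ry Rz  =>  R[1,3] = sin(thy)
  sy <- max(-1, min(1, R[1, 3]))
  if (abs(abs(sy) - 1) < 1e-10) {
    # gimbal lock: x and z rotations act about the same axis; fold the
    # whole remaining rotation into thx (R = Rx(thx) Ry(+-90) has
    # R[2,1] = +-sin(thx), R[2,2] = cos(thx))
    thy <- rad2deg(asin(sy))
    thz <- 0
    thx <- rad2deg(atan2(sign(sy) * R[2, 1], R[2, 2]))
  } else {
    thy <- rad2deg(asin(sy))
    thx <- rad2deg(atan2(-R[2, 3], R[3, 3]))
    thz <- rad2deg(atan2(-R[1, 2], R[1, 1]))
  }
  pose6(transform$t[1], transform$t[2], transform$t[3], thx, thy, thz)
}

#' Apply a rigid transform to points
#'
#' @param transform a [rigid_transform()]
#' @param points 3-vector or n x 3 matrix, mm
#' @return points of the same shape, transformed
#' @export
apply_transform <- function(transform, points) {
  p <- as_matrix3(points)
  out <- p %*% t(transform$R)
  out <- sweep(out, 2, transform$t, "+")
  if (is.null(dim(points))) out <- drop(out)
  out
}

#' Compose two rigid transforms
#'
#' `compose_transform(t1, t2)` is the transform applying `t2` first then
#' `t1` (matrix convention `T1 T2`).
#'
#' @param t1,t2 [rigid_transform()] objects
#' @return a [rigid_transform()]
#' @export
compose_transform <- function(t1, t2) {
  rigid_transform(t1$R %*% t2$R, as.numeric(t1$R %*% t2$t) + t1$t, tol = 1e-7)
}

#' Invert a rigid transform
#'
#' @param transform a [rigid_transform()]
#' @return the inverse [rigid_transform()]
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$R)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$t), tol = 1e-7)
}

#' Pose error between a true and an estimated coordinate system
#'
#' Reports six signed error components: the origin offset of the estimated
#' frame expressed in the true frame (mm) and the Cardan x-y-z decomposition
#' of the relative rotation `R_true' R_est` (degrees). Zero iff the frames
#' coincide.
#'
#' @param true_lcs,est_lcs [rigid_transform()] objects placing the true and
#'   estimated local coordinate systems in a common world frame
#' @return a [pose6()] of signed errors
#' @export
pose_error <- function(true_lcs, est_lcs) {
  dR <- t(true_lcs$R) %*% est_lcs$R
  dt <- as.numeric(t(true_lcs$R) %*% (est_lcs$t - true_lcs$t))
  transform_to_pose(rigid_transform(dR, dt, tol = 1e-7))
}

#' Least-squares rigid fit between paired point sets (Kabsch)
#'
#' Finds the proper rigid transform (no scaling, no reflection) minimizing
#' the sum of squared distances between transformed source points and their
#' paired targets, via SVD of the cross-covariance.
#'
#' @param source,target n x 3 matrices of paired points, n >= 3, not collinear
#' @return a [rigid_transform()] with attribute `rms`, the root-mean-square
#'   residual in mm
#' @export
rigid_fit <- function(source, target) {
  s <- as_matrix3(source, "source")
  t_ <- as_matrix3(target, "target")
  if (nrow(s) != nrow(t_)) stop("source and target must pair point-for-point")
  if (nrow(s) < 3) stop("degenerate configuration: need at least 3 points")
  sc <- colMeans(s); tc <- colMeans(t_)
  S <- sweep(s, 2, sc); T_ <- sweep(t_, 2, tc)
  # collinear sources leave a rotation dof unconstrained
  sv <- svd(S)$d
  if (sv[2] < 1e-8 * max(sv[1], 1)) {
    stop("degenerate configuration: source points are collinear")
  }
  H <- crossprod(S, T_)
  dec <- svd(H)
  d <- sign(det(dec$v %*% t(dec$u)))
  R <- dec$v %*% diag(c(1, 1, d)) %*% t(dec$u)
  tr <- tc - as.numeric(R %*% sc)
  fit <- rigid_transform(R, tr, tol = 1e-7)
  resid <- apply_transform(fit, s) - t_
  attr(fit, "rms") <- sqrt(mean(rowSums(resid^2)))
  fit
}
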