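#' @useDynLib cartstrain, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd cor approx pt qf setNames
#' @importFrom utils read.csv write.csv
NULL

## ---- small vector helpers -------------------------------------------------

vnorm <- function(x) sqrt(sum(x^2))

unit <- function(x) {
  n <- vnorm(x)
  if (n < 1e-300) stop("cannot normalize a zero vector")
  x / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

## wrap angle (degrees) to (-180, 180]
wrap_deg <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

## ---- rotations ------------------------------------------------------------

rot_x <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}
rot_y <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}
rot_z <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' Rotation matrix from intrinsic Z-Y'-X'' Euler angles
#'
#' Builds `R = Rz(rz) %*% Ry(ry) %*% Rx(rx)`, the convention used throughout
#' the package for 6-DOF joint decompositions. Angles are in degrees.
#'
#' @param rx,ry,rz rotations about the moving X, Y, Z axes, degrees.
#' @return 3x3 proper orthonormal matrix.
#' @export
euler_zyx_matrix <- function(rx, ry, rz) {
  rot_z(deg2rad(rz)) %*% rot_y(deg2rad(ry)) %*% rot_x(deg2rad(rx))
}

#' Intrinsic Z-Y'-X'' Euler angles of a rotation matrix
#'
#' Inverse of [euler_zyx_matrix()]. Near gimbal lock (|ry| within 1 degree of
#' 90) the decomposition is still returned but flagged.
#'
#' @param R 3x3 rotation matrix.
#' @return list with `rx`, `ry`, `rz` (degrees) and logical `gimbal_warning`.
#' @export
euler_zyx_angles <- function(R) {
  sy <- -R[3, 1]
  sy <- max(-1, min(1, sy))
  ry <- asin(sy)
  if (abs(cos(ry)) > 1e-12) {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else {
    # gimbal: rz and rx degenerate; put everything in rz
    rx <- 0
    rz <- atan2(-R[1, 2], R[2, 2])
  }
  ang <- rad2deg(c(rx, ry, rz))
  list(rx = ang[1], ry = ang[2], rz = ang[3],
       gimbal_warning = abs(abs(ang[2]) - 90) < 1)
}

## uniform random rotation (Arvo / quaternion method)
random_rotation <- function() {
  u <- runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  quat_to_matrix(q)
}

quat_to_matrix <- function(q) {
  x <- q[1]; y <- q[2]; z <- q[3]; w <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + z * w), 2 * (x * z - y * w),
    2 * (x * y - z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z + x * w),
    2 * (x * z + y * w), 2 * (y * z - x * w), 1 - 2 * (x^2 + y^2)), 3, 3)
}

## axis-angle rotation, angle in degrees
axis_angle_matrix <- function(axis, angle_deg) {
  a <- deg2rad(angle_deg)
  u <- unit(axis)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

## ---- rigid poses ----------------------------------------------------------

#' Construct a rigid pose (rotation + translation)
#'
#' A `RigidPose` maps body-frame coordinates to lab-frame coordinates:
#' `x_lab = R %*% x_body + t`.
#'
#' @param rotation 3x3 proper orthonormal matrix.
#' @param translation length-3 numeric, mm.
#' @param frame_index optional integer frame tag.
#' @param residual_rms optional fit residual, mm.
#' @return object of class `RigidPose`.
#' @export
rigid_pose <- function(rotation = diag(3), translation = c(0, 0, 0),
                       frame_index = NA_integer_, residual_rms = NA_real_) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation is not orthonormal")
  if (det(rotation) < 0)
    stop("rotation has negative determinant (reflection)")
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 frame_index = frame_index, residual_rms = residual_rms),
            class = "RigidPose")
}

#' @export
print.RigidPose <- function(x, ...) {
  ang <- euler_zyx_angles(x$rotation)
  cat(sprintf("RigidPose: t = (%.3f, %.3f, %.3f) mm, euler ZYX = (%.2f, %.2f, %.2f) deg\n",
              x$translation[1], x$translation[2], x$translation[3],
              ang$rz, ang$ry, ang$rx))
  invisible(x)
}

#' Apply a rigid pose to points
#' @param pose `RigidPose`.
#' @param points n x 3 matrix (or length-3 vector), body frame, mm.
#' @return n x 3 matrix in the lab frame.
#' @export
apply_pose <- function(pose, points) {
  p <- matrix(points, ncol = 3)
  sweep(p %*% t(pose$rotation), 2, pose$translation, "+")
}

#' Compose two rigid poses
#'
#' `compose_pose(a, b)` returns the pose equivalent to applying `b` first and
#' then `a` (i.e. `a %*% b` on homogeneous matrices).
#' @param a,b `RigidPose` objects.
#' @return `RigidPose`.
#' @export
compose_pose <- function(a, b) {
  rigid_pose(a$rotation %*% b$rotation,
             as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid pose
#' @param pose `RigidPose`.
#' @return `RigidPose` undoing `pose`.
#' @export
invert_pose <- function(pose) {
  Rt <- t(pose$rotation)
  rigid_pose(Rt, as.numeric(-Rt %*% pose$translation))
}

## ---- sphere fitting -------------------------------------------------------

#' Least-squares sphere fit
#'
#' Algebraic (Coope) least-squares fit of a sphere to points; used to derive
#' anatomical center frames of the humeral head and glenoid cavity from
#' subchondral geometry.
#'
#' @param points n x 3 matrix, n >= 4, not coplanar.
#' @return list with `center` (length 3), `radius`, and `rms` residual.
#' @export
fit_sphere <- function(points) {
  P <- as.matrix(points)
  if (nrow(P) < 4) stop("sphere fit needs at least 4 points")
  A <- cbind(2 * P, 1)
  b <- rowSums(P^2)
  sol <- tryCatch(qr.solve(A, b), error = function(e)
    stop("degenerate point set for sphere fit"))
  center <- sol[1:3]
  radius <- sqrt(sol[4] + sum(center^2))
  r_i <- sqrt(rowSums(sweep(P, 2, center)^2))
  list(center = as.numeric(center), radius = radius,
       rms = sqrt(mean((r_i - radius)^2)))
}
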