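# Rigid transforms: rotation + translation pairs acting on row-matrices of
# 3D points (x' = x R^T + t). All angles in degrees at the user surface.

#' Construct a rigid transform
#'
#' A rigid transform is a proper rotation plus a translation, applied as
#' `x' = R x + t` for column points (row points use `x %*% t(R)`).
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation numeric length-3 translation in mm.
#' @return An object of class `rigid_transform` with elements `rotation`
#'   and `translation`.
#' @examples
#' rigid_transform()                       # identity
#' rigid_transform(rotation_about("z", 10), c(1, 0, 0))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation is not orthonormal (R'R != I within 1e-9)")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be proper (det +1); got det = ", format(det(rotation)))
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- euler_angles(x$rotation)
  cat("<rigid_transform>\n")
  cat(sprintf("  translation: (%.4f, %.4f, %.4f) mm\n",
              x$translation[1], x$translation[2], x$translation[3]))
  cat(sprintf("  rotation (intrinsic X-Y-Z): phi=%.4f, theta=%.4f, psi=%.4f deg\n",
              ang["phi_x"], ang["theta_y"], ang["psi_z"]))
  invisible(x)
}

#' Elementary rotation matrix about a coordinate axis
#'
#' @param axis one of `"x"`, `"y"`, `"z"`.
#' @param angle_deg rotation angle in degrees (right-handed).
#' @return 3x3 rotation matrix.
#' @export
rotation_about <- function(axis = c("x", "y", "z"), angle_deg) {
  axis <- match.arg(axis)
  a <- angle_deg * pi / 180
  c_ <- cos(a); s_ <- sin(a)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3),
    y = matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3),
    z = matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3))
}

#' Rotation matrix from intrinsic X-Y-Z Euler angles
#'
#' Convention used throughout the package: `R = Rx(phi) %*% Ry(theta) %*% Rz(psi)`
#' (intrinsic rotations about the moving X, then Y, then Z axis).
#'
#' @param phi_x,theta_y,psi_z angles in degrees.
#' @return 3x3 rotation matrix.
#' @seealso [euler_angles()] for the inverse decomposition.
#' @export
rotation_from_euler <- function(phi_x = 0, theta_y = 0, psi_z = 0) {
  rotation_about("x", phi_x) %*% rotation_about("y", theta_y) %*%
    rotation_about("z", psi_z)
}

#' Decompose a rotation into intrinsic X-Y-Z Euler angles
#'
#' Inverse of [rotation_from_euler()]. At gimbal lock (`|theta_y|` within
#' 1e-6 degrees of 90) only the sum/difference of `phi_x` and `psi_z` is
#' determined; the tie-break sets `phi_x = 0`, folds the coupled angle into
#' `psi_z`, and flags the result.
#'
#' @param rotation 3x3 rotation matrix.
#' @return Named numeric vector `phi_x`, `theta_y`, `psi_z` in degrees, each
#'   in (-180, 180], with attribute `gimbal_lock` (logical).
#' @export
euler_angles <- function(rotation) {
  R <- rotation
  s_theta <- max(-1, min(1, R[1, 3]))
  theta <- asin(s_theta)
  lock <- abs(abs(theta) - pi / 2) < 1e-6 * pi / 180
  if (lock) {
    # R reduces to Rx(0) Ry(+-90) Rz(psi) after the phi := 0 tie-break
    phi <- 0
    psi <- atan2(R[2, 1], R[2, 2])
  } else {
    phi <- atan2(-R[2, 3], R[3, 3])
    psi <- atan2(-R[1, 2], R[1, 1])
  }
  out <- c(phi_x = phi, theta_y = theta, psi_z = psi) * 180 / pi
  attr(out, "gimbal_lock") <- lock
  out
}

#' Apply a rigid transform to points or a mesh
#'
#' @param transform a [rigid_transform()].
#' @param x an n x 3 matrix of points, a length-3 point, or a `surface_mesh`.
#' @return Object of the same type, transformed.
#' @export
transform_apply <- function(transform, x) {
  stopifnot(inherits(transform, "rigid_transform"))
  if (inherits(x, "surface_mesh")) {
    x$vertices <- transform_apply(transform, x$vertices)
    return(x)
  }
  if (is.null(dim(x))) {
    stopifnot(length(x) == 3L)
    return(drop(transform$rotation %*% x) + transform$translation)
  }
  sweep(x %*% t(transform$rotation), 2, transform$translation, "+")
}

#' Compose two rigid transforms
#'
#' `transform_compose(a, b)` returns the transform equivalent to applying
#' `b` first, then `a`.
#'
#' @param a,b [rigid_transform()] objects.
#' @return A `rigid_transform`.
#' @export
transform_compose <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  drop(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#'
#' @param transform a [rigid_transform()].
#' @return The inverse `rigid_transform`.
#' @export
transform_invert <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, drop(-Rt %*% transform$translation))
}

#' Serialize / deserialize a transform as a 4x4 homogeneous matrix
#'
#' @param transform a [rigid_transform()].
#' @return `transform_to_matrix`: a 4x4 homogeneous matrix.
#' @export
transform_to_matrix <- function(transform) {
  m <- diag(4)
  m[1:3, 1:3] <- transform$rotation
  m[1:3, 4] <- transform$translation
  m
}

#' @rdname transform_to_matrix
#' @param m a 4x4 homogeneous matrix with last row (0,0,0,1).
#' @return `transform_from_matrix`: a `rigid_transform`.
#' @export
transform_from_matrix <- function(m) {
  stopifnot(all(dim(m) == c(4L, 4L)), max(abs(m[4, ] - c(0, 0, 0, 1))) < 1e-12)
  rigid_transform(m[1:3, 1:3], m[1:3, 4])
}

# re-orthonormalize a nearly-orthonormal matrix (guards float drift in
# long compositions) via SVD projection onto SO(3)
orthonormalize_rotation <- function(R) {
  s <- svd(R)
  R2 <- s$u %*% t(s$v)
  if (det(R2) < 0) R2 <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  R2
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a near-zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
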