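#' Rigid 3-D transforms
#'
#' A `rigid_transform` is a proper rigid motion of 3-space: a rotation
#' `R` (3x3, orthonormal, `det(R) = +1`) followed by a translation `t`
#' (length-3, millimetres).  It is the currency for every spatial mapping in
#' the package: the CT-to-tracker registration, camera poses, and the true
#' pose of the patient in the world frame.
#'
#' @param rotation 3x3 rotation matrix (dimensionless).
#' @param translation numeric length-3 translation (mm).
#' @return An object of class `rigid_transform` with elements `R` and `t`.
#' @examples
#' tf <- rigid_transform(rot_axis_angle(c(0, 0, 1), pi / 2), c(1, 2, 3))
#' transform_points(tf, c(1, 0, 0))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(identical(dim(rotation), c(3L, 3L)), length(translation) == 3L)
  ortho <- max(abs(crossprod(rotation) - diag(3)))
  if (ortho >= 1e-9)
    stop("rotation is not orthonormal (max |R'R - I| = ", format(ortho), ")")
  if (abs(det(rotation) - 1) >= 1e-9)
    stop("rotation must be proper (det = +1); got det = ", format(det(rotation)))
  structure(list(R = rotation, t = translation), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n  rotation:\n")
  print(round(x$R, 6))
  cat("  translation (mm):", format(round(x$t, 4)), "\n")
  invisible(x)
}

#' Identity transform
#' @return The identity `rigid_transform`.
#' @export
rigid_identity <- function() rigid_transform(diag(3), c(0, 0, 0))

#' Rotation matrix from axis and angle
#'
#' Rodrigues' formula.  The axis is normalised internally.
#'
#' @param axis numeric length-3 rotation axis (need not be unit).
#' @param angle rotation angle in radians.
#' @return 3x3 rotation matrix.
#' @export
rot_axis_angle <- function(axis, angle) {
  axis <- as.numeric(axis)
  n <- sqrt(sum(axis^2))
  if (n == 0) stop("rotation axis must be non-zero")
  a <- axis / n
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Apply a rigid transform to points
#'
#' @param transform a `rigid_transform`.
#' @param points a numeric length-3 vector or an N x 3 matrix of points (mm).
#' @return Points of the same shape, mapped by `R p + t`.
#' @export
transform_points <- function(transform, points) {
  stopifnot(inherits(transform, "rigid_transform"))
  if (is.null(dim(points))) {
    stopifnot(length(points) == 3L)
    return(as.numeric(transform$R %*% points + transform$t))
  }
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L)
  sweep(points %*% t(transform$R), 2, transform$t, `+`)
}

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` returns the transform mapping `p` to
#' `a(b(p))` (apply `b` first).
#'
#' @param a,b `rigid_transform` objects.
#' @return The composed `rigid_transform`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(project_so3(a$R %*% b$R), as.numeric(a$R %*% b$t + a$t))
}

#' Invert a rigid transform
#' @param transform a `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$R)
  rigid_transform(Rt, as.numeric(-Rt %*% transform$t))
}

# Nearest rotation matrix (guards against drift when composing many maps).
project_so3 <- function(M) {
  s <- svd(M)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Angle of the relative rotation between two transforms
#'
#' Geodesic distance on SO(3) in radians; used by tests to quantify rotation
#' recovery error.
#'
#' @param a,b `rigid_transform` objects.
#' @return Angle in radians in `[0, pi]`.
#' @export
rotation_angle_between <- function(a, b) {
  Rrel <- t(a$R) %*% b$R
  c_ang <- (sum(diag(Rrel)) - 1) / 2
  acos(min(1, max(-1, c_ang)))
}

#' Random proper rigid transform
#'
#' Rotation drawn uniformly on SO(3) (via quaternion normal deviates),
#' translation uniform in a cube.  Uses the current RNG stream.
#'
#' @param max_translation half-width of the translation cube (mm).
#' @return A `rigid_transform`.
#' @export
random_rigid_transform <- function(max_translation = 100) {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)), 3, 3)
  rigid_transform(project_so3(R),
                  stats::runif(3, -max_translation, max_translation))
}

#' 4x4 homogeneous matrix of a rigid transform
#' @param transform a `rigid_transform`.
#' @return 4x4 numeric matrix.
#' @export
as_homogeneous <- function(transform) {
  H <- diag(4)
  H[1:3, 1:3] <- transform$R
  H[1:3, 4] <- transform$t
  H
}
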