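#' Rigid transforms
#'
#' A `RigidTransform` is a small-angle 3D rigid motion used both for phantom
#' displacement (ground truth) and as the output of landmark tracking. It
#' stores the translation in micrometres, the XYZ Euler angles in radians and
#' the corresponding rotation matrix. Angles are limited to 5 degrees: the
#' motions of interest are sub-100-micrometre patient displacements, and the
#' small-angle invariant keeps the Euler parameterization unambiguous.
#'
#' @param translation numeric length-3, micrometres.
#' @param angles numeric length-3, XYZ Euler angles in radians (each < 5 deg).
#' @return an object of class `RigidTransform` with elements `t` (3-vector),
#'   `ang` (3-vector) and `R` (3x3 rotation matrix).
#' @examples
#' tr <- rigid_transform(c(50, -30, 0))
#' pt <- transform_points(tr, cbind(0, 0, 0))
#' stopifnot(all(pt == c(50, -30, 0)))
#' @export
rigid_transform <- function(translation = c(0, 0, 0), angles = c(0, 0, 0)) {
  translation <- as.numeric(translation); angles <- as.numeric(angles)
  stopifnot(length(translation) == 3L, length(angles) == 3L,
            all(is.finite(translation)), all(is.finite(angles)))
  if (any(abs(angles) > 5 * pi / 180))
    stop("rotation angles must stay below 5 degrees (small-angle transform)",
         call. = FALSE)
  structure(list(t = translation, ang = angles, R = rot_xyz(angles)),
            class = "RigidTransform")
}

#' @export
print.RigidTransform <- function(x, ...) {
  cat(sprintf("RigidTransform: t = (%.2f, %.2f, %.2f) um, angles = (%.4f, %.4f, %.4f) deg\n",
              x$t[1], x$t[2], x$t[3],
              x$ang[1] * 180 / pi, x$ang[2] * 180 / pi, x$ang[3] * 180 / pi))
  invisible(x)
}

#' Apply a rigid transform to points
#'
#' @param transform a [rigid_transform()].
#' @param pts n x 3 matrix of points (micrometres). A n x 2 matrix is treated
#'   as lateral points at z = 0 and returned as n x 2.
#' @return transformed points, same shape as the input.
#' @export
transform_points <- function(transform, pts) {
  stopifnot(inherits(transform, "RigidTransform"))
  pts <- as.matrix(pts)
  lateral <- ncol(pts) == 2L
  if (lateral) pts <- cbind(pts, 0)
  stopifnot(ncol(pts) == 3L)
  out <- sweep(pts %*% t(transform$R), 2L, transform$t, `+`)
  if (lateral) out[, 1:2, drop = FALSE] else out
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `first`, then `second`.
#'
#' @param second,first [rigid_transform()] objects.
#' @return a `RigidTransform`.
#' @export
compose_transform <- function(second, first) {
  stopifnot(inherits(second, "RigidTransform"), inherits(first, "RigidTransform"))
  R <- second$R %*% first$R
  t <- as.numeric(second$R %*% first$t + second$t)
  structure(list(t = t, ang = ang_from_rot(R), R = R), class = "RigidTransform")
}

#' Invert a rigid transform
#'
#' @param transform a [rigid_transform()].
#' @return the inverse `RigidTransform`.
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "RigidTransform"))
  R <- t(transform$R)
  t <- as.numeric(-R %*% transform$t)
  structure(list(t = t, ang = ang_from_rot(R), R = R), class = "RigidTransform")
}
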