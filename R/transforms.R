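#' Rigid transform in 3-D patient space
#'
#' A proper rigid transform `x -> R x + t` with `R` a rotation matrix
#' (orthonormal, `det(R) = +1`) and `t` a translation in millimetres.
#' Used to carry a treatment plan from MRI space into the interventional
#' (rotational angiography) frame.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation numeric length-3 translation (mm).
#' @return An object of class `rigid_transform`.
#' @examples
#' tf <- rigid_transform(rotation_about_z(30), c(5, -3, 2))
#' pts <- matrix(rnorm(30), ncol = 3)
#' max(abs(transform_points(invert_transform(tf), transform_points(tf, pts)) - pts))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation must be orthonormal")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be proper (det = +1)")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform: rotation angle", format(rotation_angle(x), digits = 4),
      "deg, translation [", paste(format(x$translation, digits = 4), collapse = ", "),
      "] mm\n")
  invisible(x)
}

#' Elementary rotations
#'
#' Rotation matrices about the coordinate axes, angle in degrees.
#' @param angle_deg rotation angle in degrees (counter-clockwise looking
#'   down the axis).
#' @return 3x3 rotation matrix.
#' @export
rotation_about_z <- function(angle_deg) {
  a <- deg2rad(angle_deg)
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

#' @rdname rotation_about_z
#' @export
rotation_about_x <- function(angle_deg) {
  a <- deg2rad(angle_deg)
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

#' @rdname rotation_about_z
#' @export
rotation_about_y <- function(angle_deg) {
  a <- deg2rad(angle_deg)
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

#' Compose and invert rigid transforms
#'
#' `compose_transforms(a, b)` returns the transform equivalent to applying
#' `b` first and then `a`; `invert_transform` returns the inverse.
#' @param a,b,tf `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' @rdname compose_transforms
#' @export
invert_transform <- function(tf) {
  rigid_transform(t(tf$rotation), as.numeric(-t(tf$rotation) %*% tf$translation))
}

#' Rotation angle of a rigid transform
#'
#' The total rotation angle (degrees) of the rotation part, i.e. the
#' geodesic distance from the identity on SO(3). Useful for reporting
#' registration errors.
#' @param tf a `rigid_transform`.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
rotation_angle <- function(tf) {
  ctheta <- (sum(diag(tf$rotation)) - 1) / 2
  rad2deg(acos(pmin(pmax(ctheta, -1), 1)))
}

#' Apply a rigid transform to points
#'
#' @param tf a `rigid_transform`.
#' @param pts n x 3 matrix of points (mm).
#' @return n x 3 matrix of transformed points.
#' @export
transform_points <- function(tf, pts) {
  pts <- matrix(pts, ncol = 3)
  t(tf$rotation %*% t(pts) + tf$translation)
}

#' Apply a rigid transform to planning objects
#'
#' Maps every coordinate of a target plan, endocardial surface map or bare
#' point matrix through `x -> R x + t`. Scalar fields (transmurality, wall
#' thickness), labels and indices are untouched: a rigid motion does not
#' change tissue properties.
#'
#' @param obj a `target_plan`, `endo_map`, or n x 3 point matrix.
#' @param tf a `rigid_transform`.
#' @return Object of the same class with transformed coordinates.
#' @export
apply_transform <- function(obj, tf) UseMethod("apply_transform")

#' @export
apply_transform.default <- function(obj, tf) transform_points(tf, obj)

#' @export
apply_transform.endo_map <- function(obj, tf) {
  obj$vertices <- transform_points(tf, obj$vertices)
  if (!is.null(obj$normals))  # outward wall normals, stored as 3-D unit vectors
    obj$normals <- t(tf$rotation %*% t(obj$normals))
  obj
}

#' @export
apply_transform.target_plan <- function(obj, tf) {
  if (nrow(obj$targets))
    obj$targets[, c("x", "y", "z")] <- transform_points(tf, as.matrix(obj$targets[, c("x", "y", "z")]))
  obj
}

# Random rotation uniform on SO(3) (QR of a Gaussian matrix, sign-fixed).
#' @keywords internal
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
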