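#' Beam geometry
#'
#' Gantry/couch angles and the translation that place a beam (and any
#' snout-mounted accessory) relative to isocenter.
#'
#' @param gantry_angle,couch_angle degrees, interpreted modulo 360.
#' @param isocenter_translation numeric length-3, (Bx, By, Bz) mm.
#' @param snout_extension distance (mm) of the snout position from
#'   isocenter along the beam axis; must be at least the snout-to-mount
#'   offset of any mounted collimator.
#' @return An object of class `beam_geometry`.
#' @export
beam_geometry <- function(gantry_angle = 0, couch_angle = 0,
                          isocenter_translation = c(0, 0, 0),
                          snout_extension = 235) {
  stopifnot(length(isocenter_translation) == 3L,
            all(is.finite(isocenter_translation)),
            is.finite(gantry_angle), is.finite(couch_angle),
            is.finite(snout_extension))
  structure(list(
    gantry_angle = gantry_angle %% 360,
    couch_angle = couch_angle %% 360,
    isocenter_translation = as.numeric(isocenter_translation),
    snout_extension = snout_extension
  ), class = "beam_geometry")
}

#' @export
print.beam_geometry <- function(x, ...) {
  cat(sprintf("<beam_geometry> gantry %.1f deg, couch %.1f deg, snout %.1f mm, B = (%g, %g, %g) mm\n",
              x$gantry_angle, x$couch_angle, x$snout_extension,
              x$isocenter_translation[1], x$isocenter_translation[2],
              x$isocenter_translation[3]))
  invisible(x)
}

#' Homogeneous beam placement transform
#'
#' Builds the 4x4 rigid placement matrix for a beam at gantry angle
#' \eqn{\theta_g} and couch angle \eqn{\theta_c} with translation B. The
#' rotation block is
#' \deqn{R = \begin{pmatrix}
#'   \cos\theta_g\cos\theta_c & -\sin\theta_g\cos\theta_c & \sin\theta_c \\
#'   \sin\theta_g & \cos\theta_g & 0 \\
#'   -\cos\theta_g\sin\theta_c & \sin\theta_g\sin\theta_c & \cos\theta_c
#' \end{pmatrix}}
#' and the last row is (0, 0, 0, 1).
#'
#' @param geom a [beam_geometry()].
#' @return 4x4 numeric matrix (class `transform_matrix`); the upper-left
#'   3x3 block is orthonormal with determinant +1.
#' @export
beam_transform <- function(geom) {
  tg <- geom$gantry_angle * pi / 180
  tc <- geom$couch_angle * pi / 180
  b <- geom$isocenter_translation
  m <- matrix(c(
    cos(tg) * cos(tc), -sin(tg) * cos(tc), sin(tc), b[1],
    sin(tg), cos(tg), 0, b[2],
    -cos(tg) * sin(tc), sin(tg) * sin(tc), cos(tc), b[3],
    0, 0, 0, 1), nrow = 4, byrow = TRUE)
  structure(m, class = c("transform_matrix", "matrix"))
}

#' Homogeneous optimization-cylinder placement transform
#'
#' Placement matrix for a divergence-matched cylinder tilted by the
#' nominal per-axis divergences and translated to its hole position:
#' the proper rotation \eqn{R_x(\theta_y)\,R_z(\theta_x)} with translation
#' (Cx, Cy, Cz).
#'
#' @param tilt_x,tilt_y tilts in degrees (crossline divergence about the
#'   beam axis ordering below, inline divergence about the x-axis).
#' @param translation numeric length-3 (mm).
#' @return 4x4 `transform_matrix` with orthonormal rotation block.
#' @export
cylinder_transform <- function(tilt_x = 0, tilt_y = 0,
                               translation = c(0, 0, 0)) {
  tx <- tilt_x * pi / 180
  ty <- tilt_y * pi / 180
  rz <- matrix(c(cos(tx), -sin(tx), 0,
                 sin(tx), cos(tx), 0,
                 0, 0, 1), 3, 3, byrow = TRUE)
  rx <- matrix(c(1, 0, 0,
                 0, cos(ty), -sin(ty),
                 0, sin(ty), cos(ty)), 3, 3, byrow = TRUE)
  m <- diag(4)
  m[1:3, 1:3] <- rx %*% rz
  m[1:3, 4] <- as.numeric(translation)
  structure(m, class = c("transform_matrix", "matrix"))
}

#' Apply a homogeneous transform to 3D points
#'
#' @param m 4x4 transform matrix.
#' @param pts numeric matrix, n x 3.
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(m, pts) {
  pts <- as.matrix(pts)
  stopifnot(ncol(pts) == 3L, all(dim(m) == c(4L, 4L)))
  h <- cbind(pts, 1) %*% t(unclass(m))
  h[, 1:3, drop = FALSE]
}

#' Validate a rigid placement transform
#'
#' Checks the rotation-validity contract: bottom row (0,0,0,1) and an
#' orthonormal upper-left 3x3 block with determinant +1.
#'
#' @param m 4x4 matrix.
#' @param tol numeric tolerance.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
assert_rigid_transform <- function(m, tol = 1e-9) {
  stopifnot(all(dim(m) == c(4L, 4L)))
  if (max(abs(m[4, ] - c(0, 0, 0, 1))) > tol)
    stop("transform: bottom row must be (0, 0, 0, 1)", call. = FALSE)
  r <- unclass(m)[1:3, 1:3]
  if (max(abs(crossprod(r) - diag(3))) > tol)
    stop("transform: rotation block is not orthonormal", call. = FALSE)
  if (abs(det(r) - 1) > tol)
    stop("transform: rotation block must have determinant +1", call. = FALSE)
  invisible(TRUE)
}
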