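#' 2D dose plane container
#'
#' A dose (or detector-reading) plane on a regular grid. Values are
#' stored as a matrix indexed `[ix, iy]`; x runs along rows, y along
#' columns. Coordinates are mm, dose Gy unless stated otherwise.
#'
#' @param values numeric matrix `[nx, ny]`.
#' @param origin numeric length-2, coordinates of the first sample.
#' @param spacing numeric length-2, positive grid spacing.
#' @return An object of class `dose_plane`.
#' @export
dose_plane <- function(values, origin = c(0, 0), spacing = c(1, 1)) {
  values <- as.matrix(values)
  if (any(spacing <= 0)) stop("dose_plane: spacing must be positive",
                              call. = FALSE)
  if (any(!is.finite(values))) stop("dose_plane: values must be finite",
                                    call. = FALSE)
  structure(list(values = values,
                 origin = as.numeric(origin),
                 spacing = as.numeric(spacing)),
            class = "dose_plane")
}

#' @export
print.dose_plane <- function(x, ...) {
  cat(sprintf("<dose_plane> %d x %d, spacing %.3g x %.3g mm, range [%.4g, %.4g]\n",
              nrow(x$values), ncol(x$values), x$spacing[1], x$spacing[2],
              min(x$values), max(x$values)))
  invisible(x)
}

#' @rdname dose_plane
#' @param plane a `dose_plane`.
#' @export
plane_x <- function(plane) plane$origin[1] +
  (seq_len(nrow(plane$values)) - 1) * plane$spacing[1]

#' @rdname dose_plane
#' @export
plane_y <- function(plane) plane$origin[2] +
  (seq_len(ncol(plane$values)) - 1) * plane$spacing[2]

## Bilinear sample of a plane at the tensor grid xs x ys.
## Points outside the plane extent return NA.
bilinear_sample <- function(plane, xs, ys) {
  v <- plane$values
  nx <- nrow(v); ny <- ncol(v)
  fx <- (xs - plane$origin[1]) / plane$spacing[1]
  fy <- (ys - plane$origin[2]) / plane$spacing[2]
  okx <- fx >= -1e-9 & fx <= nx - 1 + 1e-9
  oky <- fy >= -1e-9 & fy <= ny - 1 + 1e-9
  fx <- pmin(pmax(fx, 0), nx - 1)
  fy <- pmin(pmax(fy, 0), ny - 1)
  i0 <- pmin(floor(fx), nx - 2); i0[nx == 1] <- 0
  j0 <- pmin(floor(fy), ny - 2); j0[ny == 1] <- 0
  wx <- fx - i0; wy <- fy - j0
  i0 <- as.integer(i0) + 1L; j0 <- as.integer(j0) + 1L
  i1 <- pmin(i0 + 1L, nx); j1 <- pmin(j0 + 1L, ny)
  out <- v[i0, j0, drop = FALSE] * outer(1 - wx, 1 - wy) +
    v[i1, j0, drop = FALSE] * outer(wx, 1 - wy) +
    v[i0, j1, drop = FALSE] * outer(1 - wx, wy) +
    v[i1, j1, drop = FALSE] * outer(wx, wy)
  out[!okx, ] <- NA_real_
  out[, !oky] <- NA_real_
  out
}

#' Resample a plane onto a target grid
#'
#' Bilinear interpolation; target points outside the source extent are
#' set to `NA` (no extrapolation).
#'
#' @param plane a [dose_plane()].
#' @param origin,spacing,dims target grid geometry (length-2 each).
#' @return A `dose_plane` on the target grid (NA outside the source).
#' @export
resample_to_common_grid <- function(plane, origin, spacing, dims) {
  if (any(spacing <= 0) || any(dims < 1))
    stop("resample_to_common_grid: degenerate target geometry", call. = FALSE)
  xs <- origin[1] + (seq_len(dims[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(dims[2]) - 1) * spacing[2]
  vals <- bilinear_sample(plane, xs, ys)
  structure(list(values = vals, origin = as.numeric(origin),
                 spacing = as.numeric(spacing)),
            class = "dose_plane")
}

#' Extract a 1D profile from a plane
#'
#' @param plane a [dose_plane()].
#' @param axis `"crossline"` (profile along x at fixed y) or `"inline"`
#'   (along y at fixed x).
#' @param offset fixed coordinate of the profile line (mm).
#' @param interpolate linear interpolation across the line (default);
#'   otherwise nearest row/column.
#' @return data.frame with `position` (mm) and `dose`.
#' @export
extract_profile <- function(plane, axis = c("crossline", "inline"),
                            offset = 0, interpolate = TRUE) {
  axis <- match.arg(axis)
  xs <- plane_x(plane); ys <- plane_y(plane)
  if (axis == "crossline") {
    if (offset < min(ys) - 1e-9 || offset > max(ys) + 1e-9)
      stop("extract_profile: offset outside plane extent", call. = FALSE)
    vals <- if (interpolate) as.numeric(bilinear_sample(plane, xs, offset))
            else plane$values[, which.min(abs(ys - offset))]
    data.frame(position = xs, dose = vals)
  } else {
    if (offset < min(xs) - 1e-9 || offset > max(xs) + 1e-9)
      stop("extract_profile: offset outside plane extent", call. = FALSE)
    vals <- if (interpolate) as.numeric(bilinear_sample(plane, offset, ys))
            else plane$values[which.min(abs(xs - offset)), ]
    data.frame(position = ys, dose = vals)
  }
}

#' 3D dose grid container
#'
#' @param values numeric array `[nx, ny, nz]`, absorbed dose (Gy).
#' @param origin,spacing numeric length-3 grid geometry (mm).
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(values, origin = c(0, 0, 0), spacing = c(1, 1, 1)) {
  if (any(spacing <= 0)) stop("dose_grid: spacing must be positive",
                              call. = FALSE)
  if (any(!is.finite(values)) || any(values < -1e-12))
    stop("dose_grid: values must be finite and non-negative", call. = FALSE)
  structure(list(values = values, origin = as.numeric(origin),
                 spacing = as.numeric(spacing), dims = dim(values)),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %s voxels, spacing %s mm, dose range [%.4g, %.4g] Gy\n",
              paste(x$dims, collapse = " x "),
              paste(signif(x$spacing, 3), collapse = " x "),
              min(x$values), max(x$values)))
  invisible(x)
}

grid_axis <- function(grid, k) grid$origin[k] +
  (seq_len(grid$dims[k]) - 1) * grid$spacing[k]

#' Extract a transverse plane from a dose grid
#'
#' @param grid a [dose_grid()].
#' @param z plane coordinate (mm) along the third grid axis; alternatively
#'   give `depth` if the grid carries a `surface_z` attribute (set by the
#'   dose engine), interpreted as depth below that surface.
#' @param depth depth in mm below the phantom surface (optional).
#' @param interpolate linearly interpolate between the two bracketing
#'   slices (default); otherwise nearest slice.
#' @return A [dose_plane()].
#' @export
extract_plane <- function(grid, z = NULL, depth = NULL, interpolate = TRUE) {
  if (is.null(z)) {
    if (is.null(depth)) stop("extract_plane: give 'z' or 'depth'",
                             call. = FALSE)
    surface <- attr(grid, "surface_z")
    if (is.null(surface)) stop("extract_plane: grid has no surface_z; use 'z'",
                               call. = FALSE)
    z <- surface - depth
  }
  zs <- grid_axis(grid, 3)
  if (z < min(zs) - 1e-9 || z > max(zs) + 1e-9)
    stop("extract_plane: plane outside grid extent", call. = FALSE)
  f <- (z - grid$origin[3]) / grid$spacing[3]
  f <- min(max(f, 0), grid$dims[3] - 1)
  if (!interpolate || abs(f - round(f)) < 1e-9) {
    vals <- grid$values[, , round(f) + 1L]
  } else {
    k0 <- floor(f); w <- f - k0
    vals <- grid$values[, , k0 + 1L] * (1 - w) + grid$values[, , k0 + 2L] * w
  }
  dose_plane(vals, origin = grid$origin[1:2], spacing = grid$spacing[1:2])
}
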