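#' Grid geometry descriptor
#'
#' Regular-grid geometry used for rasterization and dose grids.
#'
#' @param origin,spacing,dims numeric length-3 each (mm / counts).
#' @return A list with class `grid_geometry`.
#' @export
grid_geometry <- function(origin, spacing, dims) {
  if (any(spacing <= 0) || any(dims < 1))
    stop("grid_geometry: spacing must be positive and dims >= 1",
         call. = FALSE)
  structure(list(origin = as.numeric(origin), spacing = as.numeric(spacing),
                 dims = as.integer(dims)), class = "grid_geometry")
}

#' Analytic solids for planning structures
#'
#' `solid_cylinder()` describes a (possibly tilted) circular cylinder:
#' points within `radius` of the axis line through `center`, bounded
#' either by `half_length` along the axis or by a `z_range` slab (crop
#' planes perpendicular to the beam axis, the convention used for
#' optimization cylinders). `solid_cuboid()` is an axis-aligned box.
#'
#' @param center numeric length-3 (mm).
#' @param axis numeric length-3 axis direction (normalized internally).
#' @param radius cylinder radius (mm).
#' @param half_length half-length along the axis (mm), or `NULL` when
#'   `z_range` is used.
#' @param z_range length-2 z interval (mm) cropping the cylinder, or
#'   `NULL`.
#' @return A solid object (class `solid_cylinder` / `solid_cuboid`).
#' @export
solid_cylinder <- function(center, axis, radius, half_length = NULL,
                           z_range = NULL) {
  axis <- as.numeric(axis); axis <- axis / sqrt(sum(axis^2))
  if (radius <= 0) stop("solid_cylinder: radius must be > 0", call. = FALSE)
  if (is.null(half_length) && is.null(z_range))
    stop("solid_cylinder: give half_length or z_range", call. = FALSE)
  structure(list(center = as.numeric(center), axis = axis, radius = radius,
                 half_length = half_length, z_range = z_range),
            class = "solid_cylinder")
}

#' @rdname solid_cylinder
#' @param lower,upper numeric length-3 opposite corners (mm).
#' @export
solid_cuboid <- function(lower, upper) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (any(upper <= lower)) stop("solid_cuboid: upper must exceed lower",
                                call. = FALSE)
  structure(list(lower = lower, upper = upper), class = "solid_cuboid")
}

#' Point membership test for a solid
#'
#' @param solid a solid object.
#' @param pts n x 3 matrix of points (mm).
#' @return Logical vector of length n.
#' @export
solid_contains <- function(solid, pts) UseMethod("solid_contains")

#' @export
solid_contains.solid_cylinder <- function(solid, pts) {
  pts <- as.matrix(pts)
  v <- sweep(pts, 2L, solid$center)
  a <- as.numeric(v %*% solid$axis)
  rad2 <- rowSums(v^2) - a^2
  ok <- rad2 <= solid$radius^2 + 1e-12
  if (!is.null(solid$half_length)) ok <- ok & abs(a) <= solid$half_length
  if (!is.null(solid$z_range))
    ok <- ok & pts[, 3] >= solid$z_range[1] & pts[, 3] <= solid$z_range[2]
  ok
}

#' @export
solid_contains.solid_cuboid <- function(solid, pts) {
  pts <- as.matrix(pts)
  pts[, 1] >= solid$lower[1] & pts[, 1] <= solid$upper[1] &
    pts[, 2] >= solid$lower[2] & pts[, 2] <= solid$upper[2] &
    pts[, 3] >= solid$lower[3] & pts[, 3] <= solid$upper[3]
}

#' Divergence-matched optimization cylinders
#'
#' One cylinder per aperture, collinear with the hole's channel axis
#' extended into the phantom and cropped between two depths measured
#' along the beam axis from the phantom surface.
#'
#' @param spec a [collimator_spec()].
#' @param diameter cylinder diameter (mm); 5, 10 and 15 mm are the
#'   clinically explored values.
#' @param depth_range increasing depth interval (mm) for the crop.
#' @param surface_z phantom surface coordinate (mm from isocenter).
#' @return data.frame (one row per aperture) with the cylinder center
#'   `cx, cy, cz`, nominal tilts (degrees), downstream axis direction
#'   cosines `ax, ay, az`, `diameter` and axial `length`; attribute
#'   `"z_range"` carries the crop slab.
#' @export
generate_cylinders <- function(spec, diameter = 10, depth_range = c(50, 150),
                               surface_z = DEFAULT_SURFACE_Z) {
  if (diameter <= 0) stop("generate_cylinders: diameter must be > 0",
                          call. = FALSE)
  if (diff(depth_range) <= 0)
    stop("generate_cylinders: depth_range must be increasing", call. = FALSE)
  holes <- layout_holes(spec)
  z_hi <- surface_z - depth_range[1]   # shallow crop plane
  z_lo <- surface_z - depth_range[2]   # deep crop plane
  z0 <- spec$match_plane_distance
  ## downstream axis direction (unit, negative z)
  ax <- -holes$dir_x; ay <- -holes$dir_y; az <- -holes$dir_z
  t_hi <- (z0 - z_hi) / holes$dir_z
  t_lo <- (z0 - z_lo) / holes$dir_z
  t_mid <- (t_hi + t_lo) / 2
  out <- data.frame(
    row = holes$row, col = holes$col,
    cx = holes$x + t_mid * ax, cy = holes$y + t_mid * ay,
    cz = z0 + t_mid * az,
    tilt_x = holes$tilt_x, tilt_y = holes$tilt_y,
    ax = ax, ay = ay, az = az,
    diameter = diameter, length = t_lo - t_hi)
  attr(out, "z_range") <- c(z_lo, z_hi)
  attr(out, "depth_range") <- depth_range
  attr(out, "surface_z") <- surface_z
  out
}

#' Convert cylinder table rows to analytic solids
#'
#' @param cylinders output of [generate_cylinders()].
#' @return List of [solid_cylinder()] objects cropped to the depth slab.
#' @export
cylinder_solids <- function(cylinders) {
  zr <- attr(cylinders, "z_range")
  lapply(seq_len(nrow(cylinders)), function(k) {
    solid_cylinder(center = c(cylinders$cx[k], cylinders$cy[k],
                              cylinders$cz[k]),
                   axis = c(cylinders$ax[k], cylinders$ay[k],
                            cylinders$az[k]),
                   radius = cylinders$diameter[k] / 2, z_range = zr)
  })
}

#' Scoring PTV cuboid
#'
#' Axis-aligned cuboid covering all cropped optimization cylinders with a
#' lateral margin; the depth extent equals the crop interval.
#'
#' @param cylinders output of [generate_cylinders()].
#' @param margin lateral margin (mm), default 5.
#' @return A [solid_cuboid()].
#' @export
scoring_ptv <- function(cylinders, margin = 5) {
  if (is.null(cylinders) || nrow(cylinders) == 0)
    stop("scoring_ptv: empty cylinder list", call. = FALSE)
  zr <- attr(cylinders, "z_range")
  r <- cylinders$diameter / 2
  ## lateral extent of each cylinder at both crop planes
  ends <- function(zp) {
    t <- (zp - cylinders$cz) / cylinders$az
    list(x = cylinders$cx + t * cylinders$ax,
         y = cylinders$cy + t * cylinders$ay)
  }
  e1 <- ends(zr[1]); e2 <- ends(zr[2])
  solid_cuboid(
    lower = c(min(e1$x - r, e2$x - r) - margin,
              min(e1$y - r, e2$y - r) - margin, zr[1]),
    upper = c(max(e1$x + r, e2$x + r) + margin,
              max(e1$y + r, e2$y + r) + margin, zr[2]))
}

#' Rasterize a solid onto a grid
#'
#' A voxel is included iff its center lies inside the solid.
#'
#' @param solid a solid object.
#' @param geom a [grid_geometry()].
#' @return Logical array with `geom$dims`; warns and returns an all-FALSE
#'   mask when the solid misses the grid entirely.
#' @export
rasterize <- function(solid, geom) {
  xs <- geom$origin[1] + (seq_len(geom$dims[1]) - 1) * geom$spacing[1]
  ys <- geom$origin[2] + (seq_len(geom$dims[2]) - 1) * geom$spacing[2]
  zs <- geom$origin[3] + (seq_len(geom$dims[3]) - 1) * geom$spacing[3]
  pts <- as.matrix(expand.grid(x = xs, y = ys, z = zs,
                               KEEP.OUT.ATTRS = FALSE))
  mask <- array(solid_contains(solid, pts), dim = geom$dims)
  if (!any(mask))
    warning("rasterize: solid does not intersect the grid; empty mask")
  mask
}

#' Mask volume
#'
#' @param mask logical array from [rasterize()].
#' @param geom the [grid_geometry()] it was rasterized on.
#' @return Volume in mm^3.
#' @export
mask_volume <- function(mask, geom) sum(mask) * prod(geom$spacing)

#' Build a named structure set
#'
#' Rasterizes a named list of solids onto one grid geometry, keeping the
#' analytic solids alongside their voxel masks.
#'
#' @param solids named list of solid objects.
#' @param geom a [grid_geometry()].
#' @return List with `masks`, `solids` and `geometry` (class
#'   `structure_set`).
#' @export
structure_set <- function(solids, geom) {
  stopifnot(length(names(solids)) == length(solids))
  masks <- lapply(solids, rasterize, geom = geom)
  structure(list(masks = masks, solids = solids, geometry = geom),
            class = "structure_set")
}
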