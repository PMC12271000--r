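#' Synthetic pencil-beam GRID dose engine
#'
#' A deliberately simple analytic stand-in for a Monte Carlo treatment
#' planning dose calculation. A raster of Gaussian pencil spots is scanned
#' across the collimator face; spot fluence is multiplied by the aperture
#' transmission map at the collimator plane (thin-collimator
#' approximation), projected to depth from the beam's virtual source, and
#' convolved laterally with a depth-dependent Gaussian representing
#' multiple Coulomb scattering in the phantom. The depth dose is a flat
#' plateau over the stated depth range, since peak/valley structure in a
#' GRID field is governed by lateral geometry rather than the depth-dose
#' curve. Edge scatter off the channel walls is not modeled.
#'
#' @param spot_sigma lateral Gaussian sigma (mm) of an uncollimated spot
#'   at the collimator plane.
#' @param mcs_sigma_rate additional lateral sigma per cm of depth in
#'   phantom (mm/cm).
#' @param brass_transmission fraction of dose transmitted through the
#'   full-thickness block, in `[0, 1)`.
#' @param plateau_dose_per_mu open-field plateau dose per monitor unit
#'   (Gy/MU).
#' @param spot_spacing raster spot spacing (mm).
#' @param field_size raster field size (mm, length 2).
#' @return An object of class `beam_model`.
#' @export
beam_model <- function(spot_sigma = 12,
                       mcs_sigma_rate = 0.4,
                       brass_transmission = 0.005,
                       plateau_dose_per_mu = 0.01,
                       spot_spacing = 2.5,
                       field_size = c(220, 200)) {
  if (spot_sigma <= 0) stop("beam_model: spot_sigma must be > 0", call. = FALSE)
  if (brass_transmission < 0 || brass_transmission >= 1)
    stop("beam_model: brass_transmission must be in [0, 1)", call. = FALSE)
  if (spot_spacing <= 0 || mcs_sigma_rate < 0 || plateau_dose_per_mu < 0)
    stop("beam_model: invalid parameter", call. = FALSE)
  structure(list(spot_sigma = spot_sigma,
                 mcs_sigma_rate = mcs_sigma_rate,
                 brass_transmission = brass_transmission,
                 plateau_dose_per_mu = plateau_dose_per_mu,
                 spot_spacing = spot_spacing,
                 field_size = as.numeric(field_size)),
            class = "beam_model")
}

#' @export
print.beam_model <- function(x, ...) {
  cat(sprintf("<beam_model> spot sigma %.1f mm, MCS %.2f mm/cm, transmission %.3g, %.3g Gy/MU\n",
              x$spot_sigma, x$mcs_sigma_rate, x$brass_transmission,
              x$plateau_dose_per_mu))
  invisible(x)
}

#' Raster spot positions
#'
#' Symmetric rectangular raster of pencil-beam spot positions covering
#' `field_size` at `spacing`. A 100 x 100 mm field at 2.5 mm spacing
#' yields 41 x 41 = 1681 spots.
#'
#' @param field_size numeric length-2 (mm).
#' @param spacing spot spacing (mm).
#' @return data.frame with spot `x` and `y` (mm).
#' @export
spot_raster <- function(field_size, spacing) {
  if (spacing <= 0) stop("spot_raster: spacing must be > 0", call. = FALSE)
  half <- as.numeric(field_size) / 2
  xs <- seq(-half[1], half[1] + 1e-9, by = spacing)
  ys <- seq(-half[2], half[2] + 1e-9, by = spacing)
  expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
}

## default measurement setup: isocenter 10 cm deep in the phantom
DEFAULT_SURFACE_Z <- 100

## per-axis projective magnification from the collimator (match) plane to
## a transverse plane at coordinate z_p; dz shifts the collimator along z
projection_scale <- function(spec, z_p, dz = 0) {
  z_m <- spec$match_plane_distance + dz
  dlt <- z_m - z_p
  dx <- virtual_source_distance(spec$divergence_rate_x)
  dy <- virtual_source_distance(spec$divergence_rate_y)
  list(mx = (dx + dlt) / dx, my = (dy + dlt) / dy, delta = dlt)
}

#' Aperture transmission map
#'
#' Geometric transmission of the collimator on a transverse plane
#' downstream of the block: 1 inside the projected (diverged) channel
#' openings, `brass_transmission` outside. Openings are projected from
#' the per-axis virtual sources, so their centers and radii magnify with
#' distance from the match plane.
#'
#' @param spec a [collimator_spec()].
#' @param plane_z transverse plane coordinate (mm from isocenter, +z
#'   toward the snout); must be at or downstream of the (shifted) match
#'   plane.
#' @param resolution map resolution (mm).
#' @param brass_transmission transmission outside the openings.
#' @param collimator_shift numeric length-3 (mm): lateral x/y displacement
#'   of the block and longitudinal z displacement of the match plane.
#' @param xlim,ylim map extent (default: the projected block face).
#' @return A [dose_plane()] whose values lie in
#'   `[brass_transmission, 1]`.
#' @export
aperture_transmission_map <- function(spec, plane_z = 0, resolution = 1,
                                      brass_transmission = 0,
                                      collimator_shift = c(0, 0, 0),
                                      xlim = NULL, ylim = NULL) {
  prj <- projection_scale(spec, plane_z, collimator_shift[3])
  if (prj$delta < -1e-9)
    stop("aperture_transmission_map: plane is upstream of the collimator",
         call. = FALSE)
  if (is.null(xlim)) xlim <- c(-1, 1) * spec$face_width / 2 * prj$mx
  if (is.null(ylim)) ylim <- c(-1, 1) * spec$face_height / 2 * prj$my
  xs <- seq(xlim[1], xlim[2], by = resolution)
  ys <- seq(ylim[1], ylim[2], by = resolution)
  vals <- transmission_values(spec, xs, ys, prj, collimator_shift,
                              brass_transmission)
  dose_plane(vals, origin = c(xs[1], ys[1]),
             spacing = c(resolution, resolution))
}

## transmission sampled on the tensor grid xs x ys (plane coordinates);
## back-projects to the collimator plane and tests hole membership
transmission_values <- function(spec, xs, ys, prj, shift, bt) {
  holes <- layout_holes(spec)
  xc <- xs / prj$mx - shift[1]
  yc <- ys / prj$my - shift[2]
  r <- spec$hole_diameter / 2
  open <- matrix(FALSE, length(xc), length(yc))
  for (k in seq_len(nrow(holes))) {
    dx2 <- (xc - holes$x[k])^2
    dy2 <- (yc - holes$y[k])^2
    hit_x <- which(dx2 < r^2)
    if (!length(hit_x)) next
    open[hit_x, ] <- open[hit_x, ] | outer(dx2[hit_x], dy2, "+") < r^2
  }
  out <- matrix(bt, length(xc), length(yc))
  out[open] <- 1
  out
}

## separable Gaussian blur on a plane matrix, sigma in mm
gaussian_blur <- function(vals, sigma, spacing) {
  if (sigma <= 1e-9) return(vals)
  blur1 <- function(n, h) {
    k <- ceiling(4 * sigma / h)
    w <- exp(-((-k:k) * h)^2 / (2 * sigma^2))
    w <- w / sum(w)
    m <- matrix(0, n, n)
    for (d in -k:k) {
      idx <- seq_len(n)
      j <- idx + d
      ok <- j >= 1L & j <= n
      m[cbind(idx[ok], j[ok])] <- m[cbind(idx[ok], j[ok])] + w[d + k + 1L]
    }
    m
  }
  kx <- blur1(nrow(vals), spacing[1])
  ky <- blur1(ncol(vals), spacing[2])
  kx %*% vals %*% ky
}

#' Simulate a transverse GRID dose plane
#'
#' Computes the synthetic GRID dose on a transverse plane at a given
#' depth in the phantom (surface at `surface_z`, beam travelling in -z).
#'
#' @param spec a [collimator_spec()].
#' @param model a [beam_model()].
#' @param depth depth in phantom (mm).
#' @param mu delivered monitor units; dose is exactly linear in `mu`.
#' @param xlim,ylim lateral extent of the plane (mm).
#' @param spacing lateral grid spacing (mm).
#' @param collimator_shift numeric length-3 (mm) mis-positioning of the
#'   collimator: x/y lateral, z along the beam axis.
#' @param spots optional data.frame of spot positions (columns `x`, `y`)
#'   at the collimator plane; defaults to [spot_raster()] from the model.
#'   Spot positions must form a full tensor grid.
#' @param surface_z phantom surface coordinate (mm); the default places
#'   the isocenter 10 cm deep.
#' @return A [dose_plane()] (Gy).
#' @export
simulate_plane <- function(spec, model, depth = 100, mu = 100,
                           xlim = c(-110, 110), ylim = c(-110, 110),
                           spacing = 1, collimator_shift = c(0, 0, 0),
                           spots = NULL, surface_z = DEFAULT_SURFACE_Z) {
  z_p <- surface_z - depth
  prj <- projection_scale(spec, z_p, collimator_shift[3])
  if (prj$delta <= 0)
    stop("simulate_plane: plane is upstream of the collimator", call. = FALSE)
  xs <- seq(xlim[1], xlim[2], by = spacing)
  ys <- seq(ylim[1], ylim[2], by = spacing)
  if (is.null(spots)) spots <- spot_raster(model$field_size, model$spot_spacing)
  sx <- sort(unique(spots$x)); sy <- sort(unique(spots$y))

  ## back-projected plane coordinates at the collimator plane
  xc <- xs / prj$mx
  yc <- ys / prj$my
  s2 <- 2 * model$spot_sigma^2
  fx <- rowSums(exp(-outer(xc, sx, "-")^2 / s2))
  fy <- rowSums(exp(-outer(yc, sy, "-")^2 / s2))
  ## normalize so a dense open-field raster gives unit relative fluence
  norm <- 2 * pi * model$spot_sigma^2 / (model$spot_spacing^2)
  fl <- outer(fx, fy) / norm
  tr <- transmission_values(spec, xs, ys, prj, collimator_shift,
                            model$brass_transmission)
  m <- fl * tr
  sig <- model$mcs_sigma_rate * depth / 10
  m <- gaussian_blur(m, sig, c(spacing, spacing))
  dose_plane(pmax(m, 0) * model$plateau_dose_per_mu * mu,
             origin = c(xs[1], ys[1]), spacing = c(spacing, spacing))
}

#' Simulate a 3D GRID dose grid
#'
#' Stacks [simulate_plane()] slices over a depth range; dose is uniform
#' in depth within the plateau range (`phantom_depth_range`) and zero
#' outside it.
#'
#' @inheritParams simulate_plane
#' @param phantom_depth_range depth interval (mm) receiving the plateau
#'   dose.
#' @param z_spacing slice spacing (mm).
#' @param depth_range depth interval covered by the grid (defaults to the
#'   plateau range).
#' @return A [dose_grid()]; carries attribute `surface_z` so that
#'   [extract_plane()] accepts `depth = `.
#' @export
simulate_dose <- function(spec, model, phantom_depth_range = c(50, 150),
                          depth_range = phantom_depth_range,
                          xlim = c(-110, 110), ylim = c(-110, 110),
                          spacing = 2, z_spacing = 5, mu = 100,
                          collimator_shift = c(0, 0, 0),
                          surface_z = DEFAULT_SURFACE_Z) {
  if (depth_range[2] < phantom_depth_range[1] ||
      depth_range[1] > phantom_depth_range[2])
    stop("simulate_dose: grid does not intersect the plateau depth range",
         call. = FALSE)
  depths <- seq(depth_range[1], depth_range[2], by = z_spacing)
  zs <- surface_z - depths
  slices <- lapply(depths, function(d) {
    if (d < phantom_depth_range[1] - 1e-9 || d > phantom_depth_range[2] + 1e-9) {
      nx <- length(seq(xlim[1], xlim[2], by = spacing))
      ny <- length(seq(ylim[1], ylim[2], by = spacing))
      matrix(0, nx, ny)
    } else {
      simulate_plane(spec, model, depth = d, mu = mu, xlim = xlim,
                     ylim = ylim, spacing = spacing,
                     collimator_shift = collimator_shift,
                     surface_z = surface_z)$values
    }
  })
  ## grid z axis must increase; depths increase means z decreases
  arr <- simplify2array(rev(slices))
  g <- dose_grid(arr, origin = c(xlim[1], ylim[1], min(zs)),
                 spacing = c(spacing, spacing, z_spacing))
  attr(g, "surface_z") <- surface_z
  g
}

#' Projected hole centers at depth
#'
#' Projects the aperture centers from the virtual source onto a
#' transverse plane at the given depth; these are the expected GRID peak
#' positions.
#'
#' @inheritParams simulate_plane
#' @return data.frame with `row`, `col`, `x`, `y` (mm at the plane).
#' @export
projected_hole_centers <- function(spec, depth = 100,
                                   collimator_shift = c(0, 0, 0),
                                   surface_z = DEFAULT_SURFACE_Z) {
  holes <- layout_holes(spec)
  prj <- projection_scale(spec, surface_z - depth, collimator_shift[3])
  data.frame(row = holes$row, col = holes$col,
             x = (holes$x + collimator_shift[1]) * prj$mx,
             y = (holes$y + collimator_shift[2]) * prj$my)
}

#' Valley sampling points at depth
#'
#' Centroids of the hexagonal cells (triangles of three mutually nearest
#' holes), projected to the given depth: canonical valley positions for
#' PVDR estimation.
#'
#' @inheritParams projected_hole_centers
#' @return data.frame with `x`, `y` (mm at the plane).
#' @export
projected_valley_points <- function(spec, depth = 100,
                                    collimator_shift = c(0, 0, 0),
                                    surface_z = DEFAULT_SURFACE_Z) {
  holes <- layout_holes(spec)
  prj <- projection_scale(spec, surface_z - depth, collimator_shift[3])
  pts <- list()
  for (i in seq_len(spec$n_rows - 1L)) {
    a <- holes[holes$row == i, ]
    b <- holes[holes$row == i + 1L, ]
    if (nrow(a) == 0 || nrow(b) == 0) next
    for (k in seq_len(nrow(a) - 1L)) {
      x3 <- b$x[b$x > a$x[k] - 1e-9 & b$x < a$x[k + 1L] + 1e-9]
      if (length(x3) != 1L) next
      pts[[length(pts) + 1L]] <- c(
        mean(c(a$x[k], a$x[k + 1L], x3)),
        mean(c(a$y[k], a$y[k], b$y[1L])))
    }
  }
  m <- do.call(rbind, pts)
  data.frame(x = (m[, 1] + collimator_shift[1]) * prj$mx,
             y = (m[, 2] + collimator_shift[2]) * prj$my)
}
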