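#' Cumulative dose-volume histogram
#'
#' @param doses numeric vector of voxel doses (Gy), or a [dose_grid()].
#' @param mask optional logical array selecting voxels when `doses` is a
#'   grid.
#' @param bin_width histogram bin width (Gy), default 0.01.
#' @return Object of class `dvh`: `dose` (bin edges) and `volume`
#'   (fraction of the structure receiving at least that dose; starts at
#'   1, non-increasing).
#' @export
compute_dvh <- function(doses, mask = NULL, bin_width = 0.01) {
  if (inherits(doses, "dose_grid")) {
    doses <- if (is.null(mask)) as.numeric(doses$values)
             else doses$values[mask]
  } else if (!is.null(mask)) {
    doses <- doses[mask]
  }
  doses <- as.numeric(doses)
  if (length(doses) == 0) stop("compute_dvh: empty mask", call. = FALSE)
  if (any(doses < 0)) stop("compute_dvh: negative dose", call. = FALSE)
  edges <- seq(0, max(doses) + bin_width, by = bin_width)
  vol <- vapply(edges, function(d) mean(doses >= d), numeric(1))
  structure(list(dose = edges, volume = vol, n_voxels = length(doses)),
            class = "dvh")
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf("<dvh> %d voxels, dose range [0, %.3g] Gy, %d bins\n",
              x$n_voxels, max(x$dose), length(x$dose)))
  invisible(x)
}

#' @export
plot.dvh <- function(x, ...) {
  graphics::plot(x$dose, 100 * x$volume, type = "l",
                 xlab = "Dose (Gy)", ylab = "Volume (%)", ylim = c(0, 100),
                 ...)
  invisible(x)
}

#' Dose-at-volume (Dxx) from a DVH
#'
#' Dose received by at least `volume_pct`% of the structure, linearly
#' interpolated between DVH bins.
#'
#' @param dvh a [compute_dvh()] result.
#' @param volume_pct volume percentage (e.g. 90 for D90).
#' @return Dose in Gy.
#' @export
dose_at_volume <- function(dvh, volume_pct) {
  frac <- volume_pct / 100
  if (frac <= 0) return(max(dvh$dose))
  if (frac >= 1) return(dvh$dose[max(which(dvh$volume >= 1))])
  v <- dvh$volume; d <- dvh$dose
  i <- max(which(v >= frac))
  if (i == length(v)) return(d[i])
  if (v[i] == v[i + 1]) return(d[i])
  d[i] + (d[i + 1] - d[i]) * (v[i] - frac) / (v[i] - v[i + 1])
}

#' Peak-to-valley dose ratio
#'
#' Mean dose over sampling disks centered at the peak points divided by
#' the mean over disks at the valley points. Default peak points for a
#' GRID plane are the projected hole centers and default valleys the
#' hexagon cell centroids (see [projected_hole_centers()] and
#' [projected_valley_points()]); here both must be supplied explicitly.
#'
#' @param plane a [dose_plane()].
#' @param peak_points,valley_points data.frames with `x`, `y` (mm);
#'   points must lie inside the plane.
#' @param sampling_diameter disk diameter (mm), default 4.
#' @return PVDR (dimensionless).
#' @export
pvdr <- function(plane, peak_points, valley_points, sampling_diameter = 4) {
  if (nrow(peak_points) == 0 || nrow(valley_points) == 0)
    stop("pvdr: point lists must be non-empty", call. = FALSE)
  peak <- mean(vapply(seq_len(nrow(peak_points)), function(k)
    disk_mean(plane, c(peak_points$x[k], peak_points$y[k]),
              sampling_diameter / 2), numeric(1)))
  valley <- mean(vapply(seq_len(nrow(valley_points)), function(k)
    disk_mean(plane, c(valley_points$x[k], valley_points$y[k]),
              sampling_diameter / 2), numeric(1)))
  if (valley <= 0) stop("pvdr: valley mean dose is zero", call. = FALSE)
  peak / valley
}

## mean of a plane over a disk, sampled on a fine sub-grid of the disk
disk_mean <- function(plane, center, radius, step = NULL) {
  if (is.null(step)) step <- max(radius / 8, min(plane$spacing) / 4)
  u <- seq(-radius, radius, by = step)
  g <- expand.grid(dx = u, dy = u)
  g <- g[g$dx^2 + g$dy^2 <= radius^2, ]
  vals <- bilinear_sample(plane, center[1] + sort(unique(g$dx)),
                          center[2] + sort(unique(g$dy)))
  ux <- sort(unique(g$dx)); uy <- sort(unique(g$dy))
  sel <- outer(ux, uy, function(a, b) a^2 + b^2 <= radius^2)
  if (all(is.na(vals[sel])))
    stop("disk_mean: sampling disk lies outside the plane", call. = FALSE)
  mean(vals[sel], na.rm = TRUE)
}

#' Generalized equivalent uniform dose
#'
#' The generalized power mean of the voxel doses,
#' \eqn{\mathrm{gEUD} = (\frac{1}{n}\sum_i d_i^a)^{1/a}}. `a = 1` gives
#' the arithmetic mean; large positive `a` approaches the maximum dose,
#' large negative `a` the minimum. `a = 0` is rejected.
#'
#' @param doses numeric vector of voxel doses (Gy), or a [dose_grid()].
#' @param mask optional logical array when `doses` is a grid.
#' @param a gEUD exponent (required; no clinically safe default exists).
#' @return gEUD in Gy.
#' @export
geud <- function(doses, mask = NULL, a) {
  if (missing(a)) stop("geud: exponent 'a' is required", call. = FALSE)
  if (a == 0) stop("geud: a = 0 is not supported (log-limit form not used)",
                   call. = FALSE)
  if (inherits(doses, "dose_grid")) {
    doses <- if (is.null(mask)) as.numeric(doses$values)
             else doses$values[mask]
  } else if (!is.null(mask)) {
    doses <- doses[mask]
  }
  if (any(doses < 0)) stop("geud: negative dose", call. = FALSE)
  if (a < 0 && any(doses == 0)) return(0)  # power-mean limit
  ## scale by the dominant dose so large |a| cannot overflow
  s <- if (a > 0) max(doses) else min(doses)
  if (s == 0) return(0)
  s * mean((doses / s)^a)^(1 / a)
}

#' SFRT metrics report
#'
#' Computes the standard SFRT reporting set for one structure: D90, D50,
#' D20, D10, D5, Dmean, PVDR, D90/D10 and gEUD.
#'
#' @param grid a [dose_grid()].
#' @param mask logical array selecting the structure's voxels.
#' @param plane a [dose_plane()] used for the PVDR estimate.
#' @param peak_points,valley_points PVDR sampling points (see [pvdr()]).
#' @param a gEUD exponent.
#' @param contour structure name for the report row.
#' @param bin_width DVH bin width (Gy).
#' @param sampling_diameter PVDR disk diameter (mm), default 4.
#' @return One-row data.frame shaped like a clinical SFRT dose report.
#' @export
sfrt_metrics <- function(grid, mask, plane, peak_points, valley_points, a,
                         contour = "structure", bin_width = 0.01,
                         sampling_diameter = 4) {
  doses <- grid$values[mask]
  dvh <- compute_dvh(doses, bin_width = bin_width)
  dx <- function(p) dose_at_volume(dvh, p)
  data.frame(
    contour = contour,
    D90 = dx(90), D50 = dx(50), D20 = dx(20), D10 = dx(10), D5 = dx(5),
    Dmean = mean(doses),
    PVDR = pvdr(plane, peak_points, valley_points, sampling_diameter),
    D90_over_D10 = dx(90) / dx(10),
    EUD = geud(doses, a = a),
    geud_exponent = a)
}
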