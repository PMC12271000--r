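#' Detector array geometry
#'
#' Geometry of a 2D measurement device: an ionization-chamber array
#' (e.g. 32 x 32 chambers at 7.6 mm pitch over a 24.4 x 24.4 cm active
#' area) or a scintillation screen (0.5 mm pixel pitch over 30 x 30 cm).
#'
#' @param dims integer length-2, element counts.
#' @param pitch element pitch (mm).
#' @param active_area active area (mm, length 2); must agree with
#'   `dims * pitch` within one pitch.
#' @param sampling_diameter per-element disk-averaging diameter (mm);
#'   0 means point sampling.
#' @param center alignment point of the array center (mm, length 2).
#' @return Object of class `detector_geometry`.
#' @export
detector_geometry <- function(dims = c(32, 32), pitch = 7.6,
                              active_area = c(244, 244),
                              sampling_diameter = 4.5,
                              center = c(0, 0)) {
  dims <- as.integer(dims)
  if (pitch <= 0 || any(dims < 1))
    stop("detector_geometry: pitch must be positive and dims >= 1",
         call. = FALSE)
  if (any(abs(dims * pitch - active_area) > pitch))
    stop("detector_geometry: dims * pitch must match active_area within one pitch",
         call. = FALSE)
  structure(list(dims = dims, pitch = pitch,
                 active_area = as.numeric(active_area),
                 sampling_diameter = sampling_diameter,
                 center = as.numeric(center)),
            class = "detector_geometry")
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat(sprintf("<detector_geometry> %d x %d elements, pitch %.2f mm, sampling disk %.1f mm\n",
              x$dims[1], x$dims[2], x$pitch, x$sampling_diameter))
  invisible(x)
}

element_positions <- function(geom) {
  list(x = geom$center[1] + (seq_len(geom$dims[1]) - (geom$dims[1] + 1) / 2) *
         geom$pitch,
       y = geom$center[2] + (seq_len(geom$dims[2]) - (geom$dims[2] + 1) / 2) *
         geom$pitch)
}

#' Resample a dose plane onto a detector array
#'
#' Each detector element reads the mean dose over a disk of the
#' element's sampling diameter centered at its position. The model is
#' linear: readings scale exactly with a global dose scaling.
#'
#' @param plane a [dose_plane()].
#' @param geom a [detector_geometry()].
#' @return A [dose_plane()] of detector readings on the array pitch.
#' @export
resample_array <- function(plane, geom) {
  pos <- element_positions(geom)
  xr <- range(plane_x(plane)); yr <- range(plane_y(plane))
  r <- geom$sampling_diameter / 2
  if (min(pos$x) - r < xr[1] - 1e-9 || max(pos$x) + r > xr[2] + 1e-9 ||
      min(pos$y) - r < yr[1] - 1e-9 || max(pos$y) + r > yr[2] + 1e-9)
    stop("resample_array: array extends beyond the dose plane", call. = FALSE)
  vals <- matrix(NA_real_, geom$dims[1], geom$dims[2])
  if (r <= 0) {
    vals <- bilinear_sample(plane, pos$x, pos$y)
  } else {
    for (i in seq_len(geom$dims[1]))
      for (j in seq_len(geom$dims[2]))
        vals[i, j] <- disk_mean(plane, c(pos$x[i], pos$y[j]), r,
                                step = min(r / 6, min(plane$spacing) / 2))
  }
  dose_plane(vals,
             origin = c(pos$x[1], pos$y[1]),
             spacing = c(geom$pitch, geom$pitch))
}

#' Single-chamber partial-volume average
#'
#' Mean dose over voxels whose centers fall inside a disk of the chamber
#' diameter on a single grid slice: the reference value used to compare
#' an ionization-chamber reading against a calculated dose distribution
#' while accounting for partial-volume averaging.
#'
#' @param grid a [dose_grid()] (1 mm resolution recommended).
#' @param center chamber position (x, y) mm.
#' @param z slice coordinate (mm); nearest slice is used.
#' @param diameter chamber sensitive diameter (mm), default 9.9.
#' @return Mean dose (Gy) over the contoured disk.
#' @export
chamber_partial_volume <- function(grid, center, z = 0, diameter = 9.9) {
  zs <- grid_axis(grid, 3)
  k <- which.min(abs(zs - z))
  xs <- grid_axis(grid, 1); ys <- grid_axis(grid, 2)
  r <- diameter / 2
  inside <- outer((xs - center[1])^2, (ys - center[2])^2, "+") <= r^2
  if (!any(inside))
    stop("chamber_partial_volume: disk lies outside the grid", call. = FALSE)
  mean(grid$values[, , k][inside])
}

#' Percent difference between measured and planned dose
#'
#' `100 * (measured - planned) / planned`. The institutional QA rule for
#' absolute dose is `abs(percent_difference) <= 3`.
#'
#' @param measured,planned doses (same units; planned > 0).
#' @return Percent difference (full precision; round to two decimals for
#'   reporting).
#' @export
percent_difference <- function(measured, planned) {
  if (any(planned <= 0)) stop("percent_difference: planned dose must be > 0",
                              call. = FALSE)
  100 * (measured - planned) / planned
}

#' @rdname percent_difference
#' @param tolerance_pct agreement tolerance, percent (default 3).
#' @return `absolute_dose_check()`: logical, TRUE when the measurement
#'   passes the absolute-dose agreement rule.
#' @export
absolute_dose_check <- function(measured, planned, tolerance_pct = 3) {
  abs(percent_difference(measured, planned)) <= tolerance_pct
}

#' Radiochromic film calibration
#'
#' Least-squares polynomial mapping net optical density (red channel) to
#' dose. The fit is rejected unless dose is strictly monotone in OD over
#' the calibrated range; applying the calibration outside the calibrated
#' dose range flags the affected pixels.
#'
#' @param od_values net optical densities of the calibration exposures.
#' @param dose_values delivered doses (Gy).
#' @param degree polynomial degree (default 3).
#' @param dose_range valid dose range (Gy), default `c(0.25, 12)`.
#' @param through_origin constrain the fit through (0, 0).
#' @return Object of class `film_calibration` with `coefficients`
#'   (ascending powers, including the intercept), `degree` and
#'   `dose_range`.
#' @export
fit_film_calibration <- function(od_values, dose_values, degree = 3,
                                 dose_range = c(0.25, 12),
                                 through_origin = FALSE) {
  if (length(od_values) != length(dose_values))
    stop("fit_film_calibration: length mismatch", call. = FALSE)
  if (length(od_values) < degree + 1)
    stop("fit_film_calibration: need at least degree + 1 points",
         call. = FALSE)
  x <- as.numeric(od_values); y <- as.numeric(dose_values)
  if (through_origin) {
    xm <- sapply(seq_len(degree), function(p) x^p)
    fit <- stats::lm.fit(as.matrix(xm), y)
    coefs <- c(0, fit$coefficients)
  } else {
    xm <- cbind(1, sapply(seq_len(degree), function(p) x^p))
    fit <- stats::lm.fit(xm, y)
    coefs <- fit$coefficients
  }
  coefs[is.na(coefs)] <- 0
  cal <- structure(list(coefficients = unname(coefs), degree = degree,
                        dose_range = dose_range,
                        od_range = range(x)),
                   class = "film_calibration")
  ## monotonicity of dose(OD) over the calibrated OD range
  od_grid <- seq(min(x), max(x), length.out = 256)
  d_grid <- eval_poly(coefs, od_grid)
  if (any(diff(d_grid) <= 0))
    stop("fit_film_calibration: fitted dose(OD) is not strictly monotone over the calibrated range",
         call. = FALSE)
  cal
}

eval_poly <- function(coefs, x) {
  out <- 0
  for (p in seq_along(coefs)) out <- out + coefs[p] * x^(p - 1)
  out
}

#' @export
print.film_calibration <- function(x, ...) {
  cat(sprintf("<film_calibration> degree %d, dose range %.2f-%.2f Gy\n",
              x$degree, x$dose_range[1], x$dose_range[2]))
  cat("  coefficients (ascending powers):",
      paste(signif(x$coefficients, 6), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname fit_film_calibration
#' @param cal a `film_calibration`.
#' @param od_plane matrix (or [dose_plane()]) of net optical densities.
#' @return `apply_film_calibration()`: dose matrix/plane; attribute
#'   `"out_of_range"` is a logical matrix flagging pixels whose dose
#'   falls outside the calibrated range.
#' @export
apply_film_calibration <- function(cal, od_plane) {
  is_plane <- inherits(od_plane, "dose_plane")
  od <- if (is_plane) od_plane$values else as.matrix(od_plane)
  dose <- eval_poly(cal$coefficients, od)
  oor <- dose < cal$dose_range[1] - 1e-9 | dose > cal$dose_range[2] + 1e-9
  if (any(oor))
    warning(sprintf("apply_film_calibration: %d pixel(s) outside the calibrated dose range (%.2f-%.2f Gy)",
                    sum(oor), cal$dose_range[1], cal$dose_range[2]))
  if (is_plane) {
    out <- dose_plane(pmax(dose, 0), od_plane$origin, od_plane$spacing)
  } else {
    out <- dose
  }
  attr(out, "out_of_range") <- oor
  out
}

#' Scintillator saturation model
#'
#' The scintillation camera saturates above a dose ceiling set by the
#' iris opening (an iris setting of 50 corresponds to a 50 cGy ceiling).
#' Simulated counts above the ceiling are clipped and flagged.
#'
#' @param dose_plane_cgy matrix of doses in cGy.
#' @param iris_setting iris opening (percent); the saturation ceiling in
#'   cGy equals the setting.
#' @return Matrix of clipped doses with attribute `"saturated"` (logical
#'   matrix).
#' @export
apply_iris_saturation <- function(dose_plane_cgy, iris_setting = 50) {
  ceiling_cgy <- iris_setting
  sat <- dose_plane_cgy > ceiling_cgy
  out <- pmin(dose_plane_cgy, ceiling_cgy)
  attr(out, "saturated") <- sat
  out
}
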