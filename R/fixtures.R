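#' Generate synthetic test fixtures
#'
#' Writes small dose planes with known analytic properties: a uniform
#' plane, a linear ramp, a GRID-like plane built as value A on peak
#' disks over a valley floor B (so its PVDR is exactly A/B), and a
#' laterally shifted copy of the GRID plane. Used by the test-suite and
#' the demo; all randomness (pixel noise on the uniform plane's
#' noisy sibling) flows from `seed`.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed for the noisy fixture.
#' @return Named character vector of the written file paths, invisibly;
#'   the generating parameters are attached as attribute `"params"`.
#' @export
generate_fixtures <- function(dir = tempdir(), seed = 1L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(as.integer(seed))
  spacing <- c(1, 1)
  n <- 61L
  origin <- c(-(n - 1) / 2, -(n - 1) / 2)
  xs <- origin[1] + (seq_len(n) - 1)
  ys <- origin[2] + (seq_len(n) - 1)

  uniform <- dose_plane(matrix(2, n, n), origin, spacing)
  ramp <- dose_plane(outer(xs, ys, function(x, y) 1 + 0.05 * (x + 30)),
                     origin, spacing)

  peak_a <- 6; valley_b <- 1
  centers <- expand.grid(x = c(-20, 0, 20), y = c(-20, 0, 20))
  grid_vals <- matrix(valley_b, n, n)
  for (k in seq_len(nrow(centers))) {
    hit <- outer((xs - centers$x[k])^2, (ys - centers$y[k])^2, "+") <= 6^2
    grid_vals[hit] <- peak_a
  }
  grid_plane <- dose_plane(grid_vals, origin, spacing)
  shifted <- dose_plane(grid_vals, origin + c(2, 0), spacing)

  noisy <- dose_plane(matrix(2, n, n) +
                        matrix(stats::rnorm(n * n, sd = 0.02), n, n) + 0.1,
                      origin, spacing)

  paths <- c(uniform = file.path(dir, "plane_uniform.tsv"),
             ramp = file.path(dir, "plane_ramp.tsv"),
             grid = file.path(dir, "plane_grid.tsv"),
             grid_shifted = file.path(dir, "plane_grid_shifted.tsv"),
             uniform_noisy = file.path(dir, "plane_uniform_noisy.tsv"))
  write_dose_plane(uniform, paths["uniform"])
  write_dose_plane(ramp, paths["ramp"])
  write_dose_plane(grid_plane, paths["grid"])
  write_dose_plane(shifted, paths["grid_shifted"])
  write_dose_plane(noisy, paths["uniform_noisy"])
  attr(paths, "params") <- list(peak = peak_a, valley = valley_b,
                                peak_centers = centers, seed = seed,
                                shift = c(2, 0))
  invisible(paths)
}
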