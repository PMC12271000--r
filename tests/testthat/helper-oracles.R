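# Independent oracles and small builders shared across the test files.
# These deliberately re-derive quantities by different routes than the
# package code (brute force, closed forms, direct enumeration).

# brute-force 2D gamma: for every evaluated point, minimize over ALL
# reference grid points (no interpolation, no search radius)
gamma_brute_force <- function(reference, evaluated, dose_diff_pct, dta,
                              norm_dose) {
  rx <- reference$origin[1] +
    (seq_len(nrow(reference$values)) - 1) * reference$spacing[1]
  ry <- reference$origin[2] +
    (seq_len(ncol(reference$values)) - 1) * reference$spacing[2]
  ex <- evaluated$origin[1] +
    (seq_len(nrow(evaluated$values)) - 1) * evaluated$spacing[1]
  ey <- evaluated$origin[2] +
    (seq_len(ncol(evaluated$values)) - 1) * evaluated$spacing[2]
  rpts <- expand.grid(x = rx, y = ry)
  rdose <- as.numeric(reference$values)
  dd_abs <- dose_diff_pct / 100 * norm_dose
  out <- matrix(NA_real_, length(ex), length(ey))
  for (i in seq_along(ex)) {
    for (j in seq_along(ey)) {
      d2 <- (rpts$x - ex[i])^2 + (rpts$y - ey[j])^2
      dd <- (rdose - evaluated$values[i, j])^2
      out[i, j] <- sqrt(min(d2 / dta^2 + dd / dd_abs^2))
    }
  }
  out
}

# independent mesh validator: every undirected edge borders exactly two
# triangles, and the two traversals run in opposite directions
mesh_check_closed <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(cbind(tr[, 1], tr[, 2]), cbind(tr[, 2], tr[, 3]),
             cbind(tr[, 3], tr[, 1]))
  und <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  counts <- table(und)
  if (!all(counts == 2L)) return(FALSE)
  dir_keys <- paste(e[, 1], e[, 2])
  # opposite traversal <=> no directed edge repeats
  !any(duplicated(dir_keys))
}

# sort-based Dxx percentile oracle: largest dose received by at least
# pct% of the voxels
dxx_sort_oracle <- function(doses, pct) {
  s <- sort(doses, decreasing = TRUE)
  s[max(1L, floor(length(s) * pct / 100))]
}

# constant-value plane builder
const_plane <- function(value, n = 21, spacing = 1, origin = NULL) {
  if (is.null(origin)) origin <- rep(-(n - 1) * spacing / 2, 2)
  dose_plane(matrix(value, n, n), origin = origin,
             spacing = rep(spacing, 2))
}

# GRID-like plane: peaks A on disks over valley floor B
grid_like_plane <- function(peak = 6, valley = 1, n = 61,
                            centers = expand.grid(x = c(-20, 0, 20),
                                                  y = c(-20, 0, 20)),
                            radius = 6) {
  origin <- rep(-(n - 1) / 2, 2)
  xs <- origin[1] + seq_len(n) - 1
  ys <- origin[2] + seq_len(n) - 1
  vals <- matrix(valley, n, n)
  for (k in seq_len(nrow(centers))) {
    hit <- outer((xs - centers$x[k])^2, (ys - centers$y[k])^2, "+") <=
      radius^2
    vals[hit] <- peak
  }
  dose_plane(vals, origin = origin, spacing = c(1, 1))
}

# small collimator spec (3 rows) for fast dose-engine tests
small_spec <- function() {
  collimator_spec(face_width = 120, face_height = 120, n_rows = 3,
                  holes_in_full_row = 3)
}

# fast beam model for sweep tests
fast_model <- function(...) beam_model(field_size = c(140, 140), ...)
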