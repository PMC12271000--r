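#' @title Triangle mesh utilities and collimator mesh construction
#' @description
#' The collimator solid is built by direct boundary construction rather
#' than boolean CSG: each face of the block is tessellated as a set of
#' rectangular cells (one per hole, carrying an annulus between the hole
#' polygon and the cell boundary) plus filler rectangles, the channels are
#' closed with tube walls connecting the two face openings, and the four
#' side walls close the block. Shared cell boundaries use a common vertex
#' subdivision rule so the resulting mesh is watertight by construction.
#' @name mesh
NULL

new_mesh <- function(vertices, triangles) {
  structure(list(vertices = vertices, triangles = triangles),
            class = "grid_mesh")
}

#' @export
print.grid_mesh <- function(x, ...) {
  cat(sprintf("<grid_mesh> %d vertices, %d triangles, volume %.1f mm^3\n",
              nrow(x$vertices), nrow(x$triangles), mesh_volume(x)))
  invisible(x)
}

## Weld duplicated vertices (coordinates rounded to `digits`) and build
## an indexed mesh from a stacked (3*ntri) x 3 coordinate matrix.
weld_mesh <- function(coords, digits = 6) {
  key <- apply(round(coords, digits), 1L, paste, collapse = ",")
  idx <- match(key, unique(key))
  verts <- coords[!duplicated(key), , drop = FALSE]
  tris <- matrix(idx, ncol = 3L, byrow = TRUE)
  new_mesh(verts, tris)
}

#' Signed volume of a triangle mesh
#'
#' Divergence-theorem volume; positive for consistently outward-oriented
#' closed meshes.
#'
#' @param mesh a `grid_mesh`.
#' @return Volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  t1 <- v[mesh$triangles[, 1], , drop = FALSE]
  t2 <- v[mesh$triangles[, 2], , drop = FALSE]
  t3 <- v[mesh$triangles[, 3], , drop = FALSE]
  sum(t1[, 1] * (t2[, 2] * t3[, 3] - t2[, 3] * t3[, 2]) +
      t1[, 2] * (t2[, 3] * t3[, 1] - t2[, 1] * t3[, 3]) +
      t1[, 3] * (t2[, 1] * t3[, 2] - t2[, 2] * t3[, 1])) / 6
}

#' Watertightness / orientation check
#'
#' A closed, consistently oriented triangle mesh has every undirected edge
#' shared by exactly two triangles, traversed once in each direction.
#'
#' @param mesh a `grid_mesh`.
#' @return Logical scalar; attribute `"bad_edges"` carries the count of
#'   violating edges.
#' @export
mesh_is_watertight <- function(mesh) {
  tr <- mesh$triangles
  from <- c(tr[, 1], tr[, 2], tr[, 3])
  to <- c(tr[, 2], tr[, 3], tr[, 1])
  directed <- paste(from, to)
  reversed <- paste(to, from)
  ok <- !anyDuplicated(directed) &&
    all(directed %in% reversed)  # every directed edge has its mate
  n_bad <- sum(!(directed %in% reversed)) + as.integer(anyDuplicated(directed) > 0)
  structure(isTRUE(ok), bad_edges = n_bad)
}

## interior subdivision points k*h strictly inside (x0, x1)
interior_multiples <- function(x0, x1, h, tol = 1e-9) {
  ks <- seq.int(floor(x0 / h) + 1L, ceiling(x1 / h) - 1L)
  xs <- ks * h
  xs[xs > x0 + tol & xs < x1 - tol]
}

## CCW triangles (normal +z) for an axis-aligned rectangle subdivided at
## xcuts along its horizontal edges; returns stacked coordinate rows.
rect_patch <- function(x0, x1, y0, y1, xcuts, z = 0) {
  xs <- c(x0, xcuts, x1)
  out <- vector("list", length(xs) - 1L)
  for (k in seq_len(length(xs) - 1L)) {
    a <- xs[k]; b <- xs[k + 1L]
    out[[k]] <- rbind(
      c(a, y0, z), c(b, y0, z), c(b, y1, z),
      c(a, y0, z), c(b, y1, z), c(a, y1, z))
  }
  do.call(rbind, out)
}

## CCW annulus triangulation between a hole polygon (circle, n_facets
## points about `center`) and the rectangular cell boundary ring.
## Returns stacked coordinate rows. Both rings are star-shaped about the
## circle center; stitching merges them in angular order.
annulus_patch <- function(cell, center, r, n_facets, z = 0) {
  ang_in <- seq(-pi, pi, length.out = n_facets + 1L)[-(n_facets + 1L)]
  inner <- cbind(center[1] + r * cos(ang_in), center[2] + r * sin(ang_in))
  xr <- c(cell[1], interior_multiples(cell[1], cell[2], cell[5]), cell[2])
  ring <- rbind(
    cbind(xr, cell[3]),       # bottom edge, left to right (both corners)
    cbind(rev(xr), cell[4]))  # top edge, right to left (both corners)
  ang_out <- atan2(ring[, 2] - center[2], ring[, 1] - center[1])
  o <- order(ang_out)
  outer_pts <- ring[o, , drop = FALSE]
  ang_out <- ang_out[o]

  n <- nrow(inner); m <- nrow(outer_pts)
  ai <- ang_in; ao <- ang_out
  tris <- vector("list", n + m)
  i <- 1L; j <- 1L; adv_i <- 0L; adv_j <- 0L
  nexti <- function(i) if (i == n) 1L else i + 1L
  nextj <- function(j) if (j == m) 1L else j + 1L
  for (steps in seq_len(n + m)) {
    a_next_i <- ai[nexti(i)] + if (nexti(i) == 1L) 2 * pi else 0
    a_next_j <- ao[nextj(j)] + if (nextj(j) == 1L) 2 * pi else 0
    take_inner <- if (adv_i >= n) FALSE
      else if (adv_j >= m) TRUE
      else a_next_i <= a_next_j
    if (take_inner) {
      tris[[steps]] <- rbind(c(outer_pts[j, ], z),
                             c(inner[nexti(i), ], z),
                             c(inner[i, ], z))
      i <- nexti(i); adv_i <- adv_i + 1L
    } else {
      tris[[steps]] <- rbind(c(outer_pts[j, ], z),
                             c(outer_pts[nextj(j), ], z),
                             c(inner[i, ], z))
      j <- nextj(j); adv_j <- adv_j + 1L
    }
  }
  do.call(rbind, tris)
}

## Tessellate one block face (rectangle minus hole disks) at height z.
## `centers` is an n x 2 matrix of circle centers for THIS face; the cell
## decomposition always uses the nominal (reference-face) layout so both
## faces share identical cell boundaries.
face_patch <- function(spec, layout, centers, r, n_facets, z) {
  w2 <- spec$face_width / 2; h2 <- spec$face_height / 2
  py <- spec$pitch_y; h <- spec$pitch_x / 2
  parts <- list()
  if (nrow(layout) > 0) {
    y_rows <- sort(unique(layout$y))
    strip_lo <- pmax(-h2, y_rows - py / 2)
    strip_hi <- pmin(h2, y_rows + py / 2)
    ## bottom / top margin strips
    if (strip_lo[1] > -h2 + 1e-9)
      parts[[length(parts) + 1L]] <- rect_patch(
        -w2, w2, -h2, strip_lo[1], interior_multiples(-w2, w2, h), z)
    if (strip_hi[length(strip_hi)] < h2 - 1e-9)
      parts[[length(parts) + 1L]] <- rect_patch(
        -w2, w2, strip_hi[length(strip_hi)], h2,
        interior_multiples(-w2, w2, h), z)
    for (iy in seq_along(y_rows)) {
      in_row <- which(abs(layout$y - y_rows[iy]) < 1e-9)
      xs <- sort(layout$x[in_row])
      ord <- in_row[order(layout$x[in_row])]
      y0 <- strip_lo[iy]; y1 <- strip_hi[iy]
      cell_lo <- pmax(-w2, xs - h)
      cell_hi <- pmin(w2, xs + h)
      if (cell_lo[1] > -w2 + 1e-9)
        parts[[length(parts) + 1L]] <- rect_patch(
          -w2, cell_lo[1], y0, y1,
          interior_multiples(-w2, cell_lo[1], h), z)
      if (cell_hi[length(cell_hi)] < w2 - 1e-9)
        parts[[length(parts) + 1L]] <- rect_patch(
          cell_hi[length(cell_hi)], w2, y0, y1,
          interior_multiples(cell_hi[length(cell_hi)], w2, h), z)
      for (k in seq_along(xs)) {
        cell <- c(cell_lo[k], cell_hi[k], y0, y1, h)
        ctr <- centers[ord[k], ]
        if (ctr[1] - r < cell[1] || ctr[1] + r > cell[2] ||
            ctr[2] - r < cell[3] || ctr[2] + r > cell[4])
          stop(sprintf("mesh: channel opening of hole %d leaves its face cell",
                       ord[k]), call. = FALSE)
        parts[[length(parts) + 1L]] <- annulus_patch(cell, ctr, r, n_facets, z)
      }
    }
  } else {
    parts[[1L]] <- rect_patch(-w2, w2, -h2, h2, numeric(0), z)
  }
  do.call(rbind, parts)
}

## side wall quads with outward normal; `fixed` axis/value, spans and
## subdivision along `u`; z in [0, t].
wall_patch <- function(axis = c("x", "y"), value, u0, u1, ucuts, t, flip) {
  axis <- match.arg(axis)
  us <- c(u0, ucuts, u1)
  out <- vector("list", length(us) - 1L)
  for (k in seq_len(length(us) - 1L)) {
    a <- us[k]; b <- us[k + 1L]
    if (axis == "x") {
      p00 <- c(value, a, 0); p10 <- c(value, b, 0)
      p11 <- c(value, b, t); p01 <- c(value, a, t)
    } else {
      p00 <- c(a, value, 0); p10 <- c(b, value, 0)
      p11 <- c(b, value, t); p01 <- c(a, value, t)
    }
    quad <- if (flip) rbind(p10, p00, p01, p10, p01, p11)
            else rbind(p00, p10, p11, p00, p11, p01)
    out[[k]] <- quad
  }
  do.call(rbind, out)
}

#' Build the collimator block mesh
#'
#' Constructs a watertight, consistently oriented triangle mesh of the
#' collimator: the rectangular block minus one tilted circular channel per
#' hole. Channels are circles of the nominal hole diameter swept along the
#' tilted channel axis, so both face openings are exact circles; at the
#' sub-degree tilts involved this differs from a true tilted cylinder by
#' less than 0.05% in volume.
#'
#' The local frame has the downstream (reference) face in the z = 0 plane,
#' centered at the origin, with the block extending to z = `thickness`
#' (upstream, toward the virtual source).
#'
#' @param spec a [collimator_spec()].
#' @param holes hole layout as returned by [layout_holes()]; pass a
#'   zero-row data.frame for a solid block.
#' @param n_facets number of facets per channel circle (default 64).
#' @return A `grid_mesh` with `vertices` (n x 3, mm) and `triangles`
#'   (m x 3 vertex indices).
#' @export
build_collimator_mesh <- function(spec, holes = layout_holes(spec),
                                  n_facets = 64) {
  validate_collimator_spec(spec)
  if (n_facets < 8) stop("build_collimator_mesh: n_facets must be >= 8",
                         call. = FALSE)
  t <- spec$thickness
  r <- spec$hole_diameter / 2
  w2 <- spec$face_width / 2; h2 <- spec$face_height / 2
  nh <- if (is.null(holes)) 0L else nrow(holes)

  centers0 <- if (nh > 0) cbind(holes$x, holes$y) else matrix(0, 0, 2)
  ## upstream openings displaced along the channel axis
  centers1 <- if (nh > 0) {
    cbind(holes$x + t * holes$dir_x / holes$dir_z,
          holes$y + t * holes$dir_y / holes$dir_z)
  } else matrix(0, 0, 2)

  lay <- if (nh > 0) holes else data.frame(x = numeric(0), y = numeric(0))
  up <- face_patch(spec, lay, centers1, r, n_facets, z = t)
  down_ccw <- face_patch(spec, lay, centers0, r, n_facets, z = 0)
  ## downstream face outward normal is -z: reverse the winding
  ntd <- nrow(down_ccw) / 3
  flip_idx <- rep(seq_len(ntd) * 3L - 3L, each = 3L) + c(2L, 1L, 3L)
  down <- down_ccw[flip_idx, , drop = FALSE]

  tubes <- vector("list", nh)
  if (nh > 0) {
    ang <- seq(-pi, pi, length.out = n_facets + 1L)[-(n_facets + 1L)]
    ca <- cos(ang); sa <- sin(ang)
    for (k in seq_len(nh)) {
      r0 <- cbind(centers0[k, 1] + r * ca, centers0[k, 2] + r * sa, 0)
      r1 <- cbind(centers1[k, 1] + r * ca, centers1[k, 2] + r * sa, t)
      nxt <- c(seq_len(n_facets)[-1L], 1L)
      quads <- vector("list", n_facets)
      for (j in seq_len(n_facets)) {
        quads[[j]] <- rbind(r0[nxt[j], ], r0[j, ], r1[j, ],
                            r0[nxt[j], ], r1[j, ], r1[nxt[j], ])
      }
      tubes[[k]] <- do.call(rbind, quads)
    }
  }

  ## side walls: y-subdivision of x-walls at strip boundaries, and
  ## x-subdivision of y-walls at the px/2 multiples used by the faces
  py <- spec$pitch_y; h <- spec$pitch_x / 2
  ycuts <- numeric(0)
  if (nh > 0) {
    y_rows <- sort(unique(lay$y))
    ycuts <- sort(unique(c(pmax(-h2, y_rows - py / 2),
                           pmin(h2, y_rows + py / 2))))
    ycuts <- ycuts[ycuts > -h2 + 1e-9 & ycuts < h2 - 1e-9]
  }
  xcuts <- if (nh > 0) interior_multiples(-w2, w2, h) else numeric(0)
  walls <- rbind(
    wall_patch("x", w2, -h2, h2, ycuts, t, flip = FALSE),
    wall_patch("x", -w2, -h2, h2, ycuts, t, flip = TRUE),
    wall_patch("y", h2, -w2, w2, xcuts, t, flip = TRUE),
    wall_patch("y", -h2, -w2, w2, xcuts, t, flip = FALSE))

  coords <- rbind(up, down, do.call(rbind, c(tubes, list(walls))))
  weld_mesh(coords)
}

#' Analytic volume of the collimator solid
#'
#' Cuboid volume minus the per-channel volume \eqn{\pi r^2 t / \cos\theta}
#' for each tilted channel (total tilt angle \eqn{\theta}).
#'
#' @param spec a [collimator_spec()].
#' @param holes hole layout (default [layout_holes()]).
#' @return Volume in mm^3.
#' @export
collimator_volume_analytic <- function(spec, holes = layout_holes(spec)) {
  r <- spec$hole_diameter / 2
  cuboid <- spec$face_width * spec$face_height * spec$thickness
  if (is.null(holes) || nrow(holes) == 0) return(cuboid)
  cos_tilt <- holes$dir_z  # unit axis: z-component = cos(total tilt)
  cuboid - sum(pi * r^2 * spec$thickness / cos_tilt)
}

#' Collimator mass estimate
#'
#' @param spec a [collimator_spec()].
#' @param mesh optional mesh whose volume to use; defaults to the analytic
#'   cuboid-minus-channels volume.
#' @return Mass in kg (reported, not asserted against any nominal value).
#' @export
collimator_mass <- function(spec, mesh = NULL) {
  vol_mm3 <- if (is.null(mesh)) collimator_volume_analytic(spec)
             else mesh_volume(mesh)
  vol_mm3 / 1000 * spec$material_density / 1000  # mm^3 -> cm^3 -> kg
}

#' Place the collimator mesh for a beam
#'
#' Translates the mesh from its local frame (reference face at z = 0) so
#' the reference face sits `snout_extension - snout_to_mount_offset` from
#' isocenter along the beam axis, then applies the beam placement rotation
#' and translation.
#'
#' @param mesh collimator mesh in its local frame.
#' @param geom a [beam_geometry()].
#' @param spec the [collimator_spec()] (for the snout-to-mount offset).
#' @return The placed `grid_mesh`.
#' @export
place_collimator <- function(mesh, geom, spec) {
  if (geom$snout_extension < spec$snout_to_mount_offset)
    stop("place_collimator: snout_extension is smaller than the snout-to-mount offset",
         call. = FALSE)
  z_face <- geom$snout_extension - spec$snout_to_mount_offset
  v <- mesh$vertices
  v[, 3] <- v[, 3] + z_face
  m <- beam_transform(geom)
  new_mesh(apply_transform(m, v), mesh$triangles)
}
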