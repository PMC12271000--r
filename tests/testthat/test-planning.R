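test_that("default spec yields 77 cropped cylinders of ~100 mm length", {
  spec <- collimator_spec()
  cyl <- generate_cylinders(spec, diameter = 10, depth_range = c(50, 150))
  expect_equal(nrow(cyl), 77L)
  # axial length between the depth crop planes: 100 mm / cos(tilt);
  # the corner channels tilt ~4.3 degrees in total
  expect_true(all(cyl$length >= 100 - 1e-9))
  expect_true(all(cyl$length <= 100 / cos(4.5 * pi / 180)))
  expect_equal(cyl$length[abs(cyl$cx) < 1e-6 & abs(cyl$cy) < 1e-6], 100)
  expect_equal(attr(cyl, "z_range"), c(-50, 50))
  # central cylinder runs parallel to the beam axis
  ctr <- cyl[abs(cyl$cx) < 1e-6 & abs(cyl$cy) < 1e-6, ]
  expect_equal(nrow(ctr), 1L)
  expect_equal(c(ctr$ax, ctr$ay, ctr$az), c(0, 0, -1), tolerance = 1e-12)
})

test_that("cylinder axes pass through their hole centers on the reference face", {
  spec <- collimator_spec()
  holes <- layout_holes(spec)
  cyl <- generate_cylinders(spec, diameter = 10)
  z0 <- spec$match_plane_distance
  t_back <- (z0 - cyl$cz) / cyl$az
  x_at_face <- cyl$cx + t_back * cyl$ax
  y_at_face <- cyl$cy + t_back * cyl$ay
  expect_equal(x_at_face, holes$x, tolerance = 1e-6)
  expect_equal(y_at_face, holes$y, tolerance = 1e-6)
})

test_that("cylinder spacing grows with depth per projection from the virtual source", {
  spec <- collimator_spec()
  cyl <- generate_cylinders(spec, diameter = 10)
  dx <- virtual_source_distance(spec$divergence_rate_x)
  z_src <- spec$match_plane_distance + dx
  holes <- layout_holes(spec)
  for (zp in c(50, 0, -50)) {
    t_pl <- (zp - cyl$cz) / cyl$az
    x_pl <- cyl$cx + t_pl * cyl$ax
    # similar-triangles oracle from the virtual source
    oracle <- holes$x * (z_src - zp) / dx
    expect_lt(max(abs(x_pl - oracle)), 0.1)
  }
  # neighbor spacing strictly increases with depth (decreasing z)
  row5 <- which(holes$row == 5)
  sp <- sapply(c(50, -50), function(zp) {
    t_pl <- (zp - cyl$cz[row5]) / cyl$az[row5]
    diff(range(cyl$cx[row5] + t_pl * cyl$ax[row5]))
  })
  expect_gt(sp[2], sp[1])
})

test_that("scoring PTV covers all cylinders with the lateral margin", {
  spec <- collimator_spec()
  cyl <- generate_cylinders(spec, diameter = 10)
  ptv <- scoring_ptv(cyl, margin = 5)
  # depth extent equals the crop interval (10 cm)
  expect_equal(ptv$upper[3] - ptv$lower[3], 100)
  # every cylinder end circle has >= 5 mm clearance
  r <- cyl$diameter / 2
  for (zp in attr(cyl, "z_range")) {
    t_pl <- (zp - cyl$cz) / cyl$az
    x_pl <- cyl$cx + t_pl * cyl$ax
    y_pl <- cyl$cy + t_pl * cyl$ay
    expect_true(all(x_pl - r >= ptv$lower[1] + 5 - 1e-9))
    expect_true(all(x_pl + r <= ptv$upper[1] - 5 + 1e-9))
    expect_true(all(y_pl - r >= ptv$lower[2] + 5 - 1e-9))
    expect_true(all(y_pl + r <= ptv$upper[2] - 5 + 1e-9))
  }
  # single central cylinder with zero margin: 10 x 10 x 100 mm cuboid
  one <- generate_cylinders(collimator_spec(n_rows = 1,
                                            holes_in_full_row = 1),
                            diameter = 10)
  box <- scoring_ptv(one, margin = 0)
  expect_equal(box$upper - box$lower, c(10, 10, 100), tolerance = 1e-9)
  expect_error(scoring_ptv(one[0, ]), "empty")
})

test_that("rasterization volume converges to the analytic solid volume", {
  cube <- solid_cuboid(c(0, 0, 0), c(1, 1, 1))
  # grid centered on the cube: voxel-center rule recovers the volume
  geom <- grid_geometry(origin = rep(0.05, 3), spacing = rep(0.1, 3),
                        dims = rep(10, 3))
  mask <- rasterize(cube, geom)
  expect_equal(mask_volume(mask, geom), 1, tolerance = 0.01)

  # generic fractional grid offsets so the voxel-center rule is unbiased
  tilted <- solid_cylinder(center = c(0, 0, 0),
                           axis = c(sin(0.05), 0, cos(0.05)),
                           radius = 5, half_length = 50)
  geom2 <- grid_geometry(origin = c(-10.27, -10.43, -55.31),
                         spacing = c(1, 1, 1), dims = c(21, 21, 111))
  mask2 <- rasterize(tilted, geom2)
  expect_equal(mask_volume(mask2, geom2), pi * 25 * 100, tolerance = 0.02)

  far <- solid_cuboid(c(500, 500, 500), c(501, 501, 501))
  expect_warning(m3 <- rasterize(far, geom2), "does not intersect")
  expect_false(any(m3))
})

test_that("cropping commutes with rasterization on voxel centers", {
  spec <- collimator_spec()
  cyl <- generate_cylinders(spec, diameter = 10)
  k <- which(cyl$row == 5 & cyl$col == 9)  # an edge cylinder, tilted
  geom <- grid_geometry(origin = c(cyl$cx[k] - 10, cyl$cy[k] - 10, -60),
                        spacing = c(1, 1, 1), dims = c(21, 21, 121))
  cropped <- cylinder_solids(cyl)[[k]]
  uncropped <- solid_cylinder(center = c(cyl$cx[k], cyl$cy[k], cyl$cz[k]),
                              axis = c(cyl$ax[k], cyl$ay[k], cyl$az[k]),
                              radius = 5, half_length = 1e4)
  m_crop <- rasterize(cropped, geom)
  m_full <- rasterize(uncropped, geom)
  zs <- geom$origin[3] + (seq_len(geom$dims[3]) - 1) * geom$spacing[3]
  zr <- attr(cyl, "z_range")
  slab <- array(rep(zs >= zr[1] & zs <= zr[2],
                    each = geom$dims[1] * geom$dims[2]), dim = geom$dims)
  expect_identical(m_crop, m_full & slab)
})

test_that("structure sets rasterize every named solid", {
  one <- generate_cylinders(collimator_spec(n_rows = 1,
                                            holes_in_full_row = 1),
                            diameter = 10)
  geom <- grid_geometry(origin = c(-12, -12, -55), spacing = c(2, 2, 5),
                        dims = c(13, 13, 23))
  ss <- structure_set(list(cyl = cylinder_solids(one)[[1]],
                           ptv = scoring_ptv(one, margin = 2)), geom)
  expect_named(ss$masks, c("cyl", "ptv"))
  expect_true(all(sapply(ss$masks, any)))
  # the PTV contains the cylinder
  expect_true(all(ss$masks$ptv[ss$masks$cyl]))
})
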