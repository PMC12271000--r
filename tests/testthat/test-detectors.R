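test_that("chamber-array geometry matches the stated active area", {
  geom <- detector_geometry()
  expect_equal(geom$dims, c(32L, 32L))
  # 32 x 7.6 mm = 243.2 mm, within one pitch of the 244 mm active area
  expect_lt(abs(geom$dims[1] * geom$pitch - geom$active_area[1]),
            geom$pitch)
  expect_error(detector_geometry(dims = c(32, 32), pitch = 7.6,
                                 active_area = c(300, 300)),
               "active_area")
  lynx <- detector_geometry(dims = c(600, 600), pitch = 0.5,
                            active_area = c(300, 300),
                            sampling_diameter = 0)
  expect_equal(lynx$pitch, 0.5)
})

test_that("array readings average uniform planes exactly and scale linearly", {
  plane <- const_plane(7.25, n = 101)
  geom <- detector_geometry(dims = c(5, 5), pitch = 7.6,
                            active_area = c(38, 38),
                            sampling_diameter = 4.5)
  r <- resample_array(plane, geom)
  expect_true(all(abs(r$values - 7.25) < 1e-9))
  # linearity under global scaling
  p2 <- dose_plane(plane$values * 3.7, plane$origin, plane$spacing)
  r2 <- resample_array(p2, geom)
  expect_equal(r2$values, r$values * 3.7, tolerance = 1e-9)
  big <- detector_geometry(dims = c(32, 32), pitch = 7.6,
                           active_area = c(244, 244))
  expect_error(resample_array(plane, big), "beyond")
})

test_that("a chamber centered on a Gaussian peak reads the disk average", {
  sigma <- 6; R <- 2.25
  xs <- seq(-25, 25, 0.25)
  plane <- dose_plane(outer(exp(-xs^2 / (2 * sigma^2)),
                            exp(-xs^2 / (2 * sigma^2))),
                      origin = c(-25, -25), spacing = c(0.25, 0.25))
  geom <- detector_geometry(dims = c(1, 1), pitch = 7.6,
                            active_area = c(7.6, 7.6),
                            sampling_diameter = 2 * R)
  reading <- resample_array(plane, geom)$values[1, 1]
  # closed-form disk average of a radial Gaussian
  analytic <- (2 * sigma^2 / R^2) * (1 - exp(-R^2 / (2 * sigma^2)))
  expect_equal(reading / analytic, 1, tolerance = 0.005)
  # averaging a peaked field reads below the point maximum
  expect_lt(reading, 1)
})

test_that("partial-volume chamber averaging matches its contracts", {
  nx <- 41
  xs <- seq(-20, 20, 1)
  uniform <- dose_grid(array(7.245, dim = c(nx, nx, 3)),
                       origin = c(-20, -20, -1), spacing = c(1, 1, 1))
  expect_equal(chamber_partial_volume(uniform, c(0, 0), z = 0), 7.245)
  # linear lateral gradient: symmetric disk reads the center value
  grad_vals <- array(rep(5 + 0.1 * xs, times = nx * 3), dim = c(nx, nx, 3))
  grad <- dose_grid(grad_vals, origin = c(-20, -20, -1),
                    spacing = c(1, 1, 1))
  expect_equal(chamber_partial_volume(grad, c(0, 0), z = 0), 5,
               tolerance = 0.001 * 5)
  # peaked dose: mean below the peak point dose
  peak_vals <- array(outer(exp(-xs^2 / 50), exp(-xs^2 / 50)),
                     dim = c(nx, nx, 3))
  peaked <- dose_grid(peak_vals, origin = c(-20, -20, -1),
                      spacing = c(1, 1, 1))
  pv <- chamber_partial_volume(peaked, c(0, 0), z = 0, diameter = 9.9)
  expect_lt(pv, 1)
  # shrinking the chamber converges to the point dose
  diffs <- sapply(c(9.9, 5, 2.1), function(dm)
    abs(chamber_partial_volume(peaked, c(0, 0), z = 0, diameter = dm) - 1))
  expect_true(all(diff(diffs) < 0))
  expect_error(chamber_partial_volume(uniform, c(500, 500), z = 0),
               "outside")
})

test_that("percent difference reproduces the commissioning chamber results", {
  expect_equal(round(percent_difference(739.78, 724.5), 2), 2.11)
  expect_equal(round(percent_difference(43.95, 43.0), 2), 2.21)
  expect_equal(percent_difference(5, 5), 0)
  expect_error(percent_difference(1, 0), "planned")
  # institutional absolute-dose rule: both plans pass at 3%
  expect_true(absolute_dose_check(739.78, 724.5))
  expect_true(absolute_dose_check(43.95, 43.0))
  expect_false(absolute_dose_check(110, 100))
})

test_that("film calibration recovers a generating cubic and flags range", {
  od <- seq(0.05, 1.2, length.out = 12)
  coefs <- c(0.2, 5, 2, 1)
  dose <- coefs[1] + coefs[2] * od + coefs[3] * od^2 + coefs[4] * od^3
  cal <- fit_film_calibration(od, dose, degree = 3)
  expect_equal(cal$coefficients, coefs, tolerance = 1e-6)
  # application reproduces the doses within the calibrated range
  back <- apply_film_calibration(cal, matrix(od, 3, 4))
  expect_equal(as.numeric(back), dose, tolerance = 1e-6)
  expect_false(any(attr(back, "out_of_range")))
  # an OD mapping to ~13 Gy exceeds the 12 Gy calibrated ceiling
  expect_warning(out <- apply_film_calibration(cal, matrix(1.36)),
                 "outside the calibrated")
  expect_true(all(attr(out, "out_of_range")))
  # through-origin constraint maps zero OD to zero dose
  cal0 <- fit_film_calibration(od, 5 * od + 2 * od^2, degree = 2,
                               through_origin = TRUE)
  expect_equal(suppressWarnings(apply_film_calibration(cal0, matrix(0)))[1],
               0, tolerance = 1e-9)
  # non-monotone OD-dose data is rejected
  bad_dose <- sin(od * 6) + 2
  expect_error(fit_film_calibration(od, bad_dose, degree = 3), "monotone")
  expect_error(fit_film_calibration(od[1:3], dose[1:3], degree = 3),
               "degree")
})

test_that("the iris ceiling saturates and flags scintillator readings", {
  doses <- matrix(c(10, 49.9, 50, 50.1, 80, 5), 2, 3)
  out <- apply_iris_saturation(doses, iris_setting = 50)
  expect_true(all(out <= 50))
  expect_equal(attr(out, "saturated"),
               matrix(c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE), 2, 3))
  expect_equal(out[doses <= 50], doses[doses <= 50])
})
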