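test_that("a plane compared against itself passes everywhere with gamma 0", {
  p <- grid_like_plane()
  res <- gamma_2d(p, p, gamma_criteria())
  expect_equal(res$pass_rate, 100)
  expect_true(all(res$gamma_map[!is.na(res$gamma_map)] < 1e-9))
})

test_that("a uniform +3% offset sits exactly on the gamma boundary", {
  p <- grid_like_plane()
  up <- dose_plane(p$values * 1.03, p$origin, p$spacing)
  res <- gamma_2d(p, up, gamma_criteria(dose_diff = 3, dta = 3,
                                        low_dose_threshold = 0))
  # global normalization: gamma = 1 exactly at the reference maximum,
  # < 1 below it; boundary points pass
  expect_equal(max(res$gamma_map, na.rm = TRUE), 1, tolerance = 1e-9)
  expect_equal(res$pass_rate, 100)
})

test_that("gamma matches the exhaustive brute-force oracle on random planes", {
  set.seed(42)
  for (rep in 1:3) {
    ref <- dose_plane(matrix(runif(21 * 21, 1, 10), 21, 21),
                      origin = c(-10, -10), spacing = c(1, 1))
    ev <- dose_plane(ref$values + matrix(rnorm(441, sd = 0.3), 21, 21),
                     origin = c(-10, -10), spacing = c(1, 1))
    ev$values <- pmax(ev$values, 0)
    crit <- gamma_criteria(dose_diff = 3, dta = 3, low_dose_threshold = 0,
                           normalization = max(ref$values))
    # search restricted to the reference sample grid = brute force
    res <- gamma_2d(ref, ev, crit, search_step = 1, search_radius = 30)
    oracle <- gamma_brute_force(ref, ev, 3, 3, max(ref$values))
    expect_lt(max(abs(res$gamma_map - oracle)), 1e-6)
  }
})

test_that("raising the threshold to 50% rescues valley-dominated failures", {
  ref <- grid_like_plane(peak = 6, valley = 1)
  # corrupt the valleys by +25%: failures concentrate below 50% of max
  ev_vals <- ifelse(ref$values < 3, ref$values * 1.25, ref$values)
  ev <- dose_plane(ev_vals, ref$origin, ref$spacing)
  r10 <- gamma_2d(ref, ev, gamma_criteria(low_dose_threshold = 10))
  r50 <- gamma_2d(ref, ev, gamma_criteria(low_dose_threshold = 50))
  expect_gte(r50$pass_rate, r10$pass_rate)
  expect_gt(r50$pass_rate, 99)
  expect_lt(r10$pass_rate, 90)
})

test_that("gamma is not symmetric when reference and evaluated swap roles", {
  # normalization and threshold follow the reference plane
  ref <- const_plane(1, n = 21)
  ref$values[11, 11] <- 2
  ev <- dose_plane(ref$values * 1.04, ref$origin, ref$spacing)
  crit <- gamma_criteria(dose_diff = 3, dta = 1, low_dose_threshold = 0)
  fwd <- gamma_2d(ref, ev, crit)
  bwd <- gamma_2d(ev, ref, crit)
  expect_false(isTRUE(all.equal(fwd$pass_rate, bwd$pass_rate)))
})

test_that("finer search subsampling barely moves the pass rate on smooth planes", {
  xs <- seq(-15, 15, 1)
  ref <- dose_plane(outer(exp(-xs^2 / 200), exp(-xs^2 / 200)) * 5,
                    origin = c(-15, -15), spacing = c(1, 1))
  ev <- dose_plane(ref$values * 1.02, ref$origin, ref$spacing)
  crit <- gamma_criteria(low_dose_threshold = 10)
  coarse <- gamma_2d(ref, ev, crit, search_step = 0.3)
  fine <- gamma_2d(ref, ev, crit, search_step = 0.15)
  expect_lt(abs(coarse$pass_rate - fine$pass_rate), 0.1)
})

test_that("count normalization scales the maximum pixel to exactly 100", {
  m <- matrix(c(250, 500, 1000, 0), 2, 2)
  nm <- normalize_counts(m)
  expect_equal(max(nm), 100)
  expect_equal(sort(as.numeric(nm)), c(0, 25, 50, 100))
  expect_equal(normalize_counts(matrix(7, 3, 3)),
               matrix(100, 3, 3))
  expect_error(normalize_counts(matrix(0, 2, 2)), "zero")
  expect_error(normalize_counts(matrix(-1, 2, 2)), "non-negative")
})

test_that("resampling is exact for linear ramps and identity geometries", {
  xs <- 0:20
  ramp <- dose_plane(outer(xs, xs, function(a, b) 1 + 0.3 * a + 0.1 * b),
                     origin = c(0, 0), spacing = c(1, 1))
  same <- resample_to_common_grid(ramp, c(0, 0), c(1, 1), c(21, 21))
  expect_equal(same$values, ramp$values, tolerance = 1e-12)
  half <- resample_to_common_grid(ramp, c(0, 0), c(0.5, 0.5), c(41, 41))
  hx <- seq(0, 20, 0.5)
  expect_equal(half$values,
               outer(hx, hx, function(a, b) 1 + 0.3 * a + 0.1 * b),
               tolerance = 1e-12)
  # constant plane stays constant on any interior geometry
  cp <- const_plane(3, n = 11)
  rs <- resample_to_common_grid(cp, c(-4.7, -3.1), c(0.9, 1.7), c(9, 4))
  expect_true(all(abs(rs$values - 3) < 1e-12))
  # outside the source: NA, not extrapolated
  out <- resample_to_common_grid(cp, c(0, 0), c(10, 10), c(3, 3))
  expect_true(any(is.na(out$values)))
  expect_error(resample_to_common_grid(cp, c(0, 0), c(0, 1), c(3, 3)),
               "degenerate")
})

test_that("invalid gamma inputs are rejected", {
  p <- const_plane(1)
  far <- dose_plane(matrix(1, 5, 5), origin = c(500, 500), spacing = c(1, 1))
  expect_error(gamma_2d(p, far), "overlap")
  z <- const_plane(0)
  expect_error(gamma_2d(z, z), "normalization")
  expect_error(gamma_criteria(dose_diff = 0), "positive")
  expect_error(gamma_criteria(low_dose_threshold = 100), "threshold")
})
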