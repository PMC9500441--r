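test_that("volume is voxel count times voxel volume and rotation-invariant", {
  vox <- cbind(rep(1:10, 100), rep(1:10, each = 100), rep(1:10, 100))
  expect_equal(compute_volume(vox[1:1000, ], c(2, 2, 2)), 8000)
  expect_error(compute_volume(vox[0, ], c(2, 2, 2)), "empty")

  arr <- array(FALSE, c(40, 40, 40))
  arr <- paint_sphere(array(0, c(40, 40, 40)), c(1, 1, 1), c(20, 20, 20), 10, 1) > 0
  v <- compute_volume(arr, c(1, 1, 1))
  expect_equal(v, 4 / 3 * pi * 10^3, tolerance = 0.03)
  expect_equal(compute_volume(aperm(arr, c(3, 1, 2)), c(1, 1, 1)), v)
})

test_that("moment ellipsoid recovers sphere and prolate spheroid axes within 5%", {
  sph <- paint_sphere(array(0, c(50, 50, 50)), c(1, 1, 1), c(25, 25, 25), 20, 1) > 0
  ax <- fit_ellipsoid(sph, c(1, 1, 1))
  expect_equal(ax, rep(20, 3), tolerance = 0.05)

  sphero <- paint_ellipsoid(array(0, c(50, 50, 110)), c(1, 1, 2),
                            c(25, 25, 110), c(20, 20, 100), 1) > 0
  ax2 <- fit_ellipsoid(sphero, c(1, 1, 2))
  expect_equal(ax2, c(20, 20, 100), tolerance = 0.05)

  # rigid 90-degree rotation leaves the axes unchanged
  ax3 <- fit_ellipsoid(aperm(sphero, c(3, 2, 1)), c(2, 1, 1))
  expect_equal(ax3, ax2, tolerance = 0.02)

  plane <- cbind(1:10, rep(1, 10), rep(1, 10))
  expect_error(fit_ellipsoid(plane, c(1, 1, 1)), "degenerate|voxels")
})

test_that("prolate ellipticity follows (c-b)/(c-a) with the sphere convention", {
  expect_equal(ellipticity_prolate(2, 2, 2), 0)
  expect_equal(ellipticity_prolate(1, 1, 5), 1)
  expect_equal(ellipticity_prolate(1, 2, 3), 0.5)
  expect_error(ellipticity_prolate(0, 1, 2), "positive")
  expect_error(ellipticity_prolate(3, 2, 1), "a <= b <= c")
  # pluggable strategy: an alternative definition can be swapped in
  alt <- function(a, b, c) 1 - a / c
  lm <- segmented(straight_phantom())
  m <- measure_crypts(lm, ellipticity_fun = alt)
  expect_equal(m$ellipticity_prolate, 1 - m$semi_a / m$semi_c)
})

test_that("depth clipping enforces the 250-um normalization", {
  deep <- rasterize_specimen(
    crypt_spec(1, 100, 100, depth = 380, tube_radius = 35, goblet_density = 0),
    shape = c(50, 50, 100), voxel_size = 4, seed = 11
  )
  lm <- segment_crypts(deep$volumes$PAFhy, slice_interval = 13)
  vox <- clip_to_depth(lm, 1, max_depth = 250)
  span <- diff(range(vox[, 3]) + c(-0.5, 0.5)) * 4
  expect_lte(span, 250 + 4)
  expect_gt(span, 0.9 * 250)
  expect_equal(compute_volume(vox, rep(4, 3)), pi * 35^2 * 250, tolerance = 0.05)

  shallow <- clip_to_depth(segmented(straight_phantom()), 1, max_depth = 400)
  unclipped <- clip_to_depth(segmented(straight_phantom()), 1, max_depth = 250)
  expect_equal(nrow(shallow), nrow(unclipped))
  expect_error(clip_to_depth(lm, 99), "empty crypt")
})

test_that("centerline centroids are faithful for straight, tilted and helical crypts", {
  lms <- segmented(straight_phantom())
  cl <- extract_centerline(clip_to_depth(lms, 1), lms$voxel_size)
  expect_equal(nrow(cl), 6)
  expect_lt(diff(range(cl$x_um)), 1)
  expect_lt(diff(range(cl$y_um)), 1)

  tilted <- rasterize_specimen(
    crypt_spec(1, 80, 100, depth = 240, tube_radius = 30, axis_tilt = 10,
               goblet_density = 0),
    shape = c(64, 50, 64), voxel_size = 4, seed = 12
  )
  lmt <- segment_crypts(tilted$volumes$PAFhy, slice_interval = 13)
  clt <- extract_centerline(clip_to_depth(lmt, 1), lmt$voxel_size)
  fit <- stats::lm(clt$x_um ~ clt$z_um)
  expect_lt(max(abs(residuals(fit))), 4)  # collinear within one voxel

  ph <- helix_phantom()
  lmh <- segmented(ph)
  clh <- extract_centerline(clip_to_depth(lmh, 1), lmh$voxel_size)
  truth <- generate_centerline(ph$crypt_specs[1, ], 50)
  expect_true(all(abs(clh$x_um - truth$x_um) < 2.5))
  expect_true(all(abs(clh$y_um - truth$y_um) < 2.5))
})

test_that("tortuosity matches the six-point chord arithmetic exactly", {
  # straight-line identity
  straight <- tibble::tibble(z_um = seq(0, 250, 50), x_um = 3, y_um = -2)
  expect_equal(tortuosity(straight), 1.0)

  # helix r = 40 um, one turn over 250 um: each of the five chords is
  # sqrt(50^2 + (2 * 40 * sin(36 deg))^2), the end chord is 250
  cl <- generate_centerline(
    crypt_spec(1, 0, 0, depth = 250, tube_radius = 30,
               helix_radius = 40, helix_turns = 1), 50)
  seg <- sqrt(50^2 + (2 * 40 * sin(pi / 5))^2)
  expect_equal(tortuosity(cl), 5 * seg / 250, tolerance = 1e-9)

  # scale invariance
  doubled <- dplyr::mutate(cl, dplyr::across(dplyr::everything(), ~ .x * 2))
  expect_equal(tortuosity(doubled), tortuosity(cl), tolerance = 1e-12)

  # coincident endpoints are undefined
  loop <- tibble::tibble(z_um = c(0, 50, 0), x_um = c(0, 10, 0), y_um = 0)
  expect_error(tortuosity(loop), "coincident")
})

test_that("tortuosity is at least 1 and equals 1 only for collinear points", {
  set.seed(31)
  for (i in 1:25) {
    pts <- cbind(runif(6, -30, 30), runif(6, -30, 30), seq(0, 250, 50))
    expect_gte(tortuosity(pts), 1)
  }
  tilted <- cbind(seq(0, 50, 10), seq(0, 25, 5), seq(0, 250, 50))
  expect_equal(tortuosity(tilted), 1, tolerance = 1e-9)
})

test_that("morphometry recovers analytic truth on zero-noise crypts", {
  for (seed in c(3, 14)) {
    ph <- small_helix(seed, turns = 0.8)
    m <- measure_crypts(segment_crypts(ph$volumes$PAFhy, slice_interval = 13))
    tr <- ph$truth
    expect_equal(m$volume_um3, tr$volume_um3, tolerance = 0.05)
    expect_equal(m$tortuosity, tr$tortuosity, tolerance = 0.02)
    expect_lt(abs(m$ellipticity_prolate - tr$ellipticity_prolate), 0.05)
  }
})

test_that("descriptors are invariant under in-plane translation of the specimen", {
  base <- crypt_spec(1, 90, 90, depth = 250, tube_radius = 35,
                     helix_radius = 20, helix_turns = 0.7, goblet_density = 0)
  shifted <- dplyr::mutate(base, base_x = base_x + 24, base_y = base_y - 16)
  m1 <- measure_crypts(segment_crypts(
    rasterize_specimen(base, shape = c(64, 64, 66), voxel_size = 4,
                       seed = 9)$volumes$PAFhy))
  m2 <- measure_crypts(segment_crypts(
    rasterize_specimen(shifted, shape = c(64, 64, 66), voxel_size = 4,
                       seed = 9)$volumes$PAFhy))
  expect_equal(m1$volume_um3, m2$volume_um3, tolerance = 0.02)
  expect_equal(m1$tortuosity, m2$tortuosity, tolerance = 0.01)
  expect_equal(m1$ellipticity_prolate, m2$ellipticity_prolate, tolerance = 0.02)
})
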