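# cryptitis phantom shared across the detection tests
cryptitis_case <- function(seed = 9, count = 12, bias = 0.8) {
  sp <- crypt_spec(1, 120, 120, depth = 220, tube_radius = 45,
                   lumen_fraction = 0.6, goblet_density = 4)
  infl <- inflammation_spec(1, "cryptitis", neutrophil_count = count,
                            placement_bias = bias)
  ph <- rasterize_specimen(sp, infl, shape = c(120, 120, 120), voxel_size = 2,
                           seed = seed)
  lm <- segment_crypts(ph$volumes$PAFhy, slice_interval = 13)
  list(ph = ph, lm = lm)
}

test_that("detection count equals the planted count on zero-noise phantoms", {
  for (seed in c(9, 21, 33)) {
    cs <- cryptitis_case(seed)
    cells <- detect_neutrophils(cs$ph$volumes$PAFhy, cs$lm)
    expect_equal(nrow(cells), 12)
    expect_true(all(cells$volume_um3 >= neutrophil_size_window()[1] &
                    cells$volume_um3 <= neutrophil_size_window()[2]))
  }
})

test_that("goblet mucus and the membrane fall outside the cell gate", {
  sp <- crypt_spec(1, 120, 120, depth = 220, tube_radius = 45,
                   lumen_fraction = 0.6, goblet_density = 8)
  ph <- rasterize_specimen(sp, shape = c(120, 120, 120), voxel_size = 2, seed = 13)
  lm <- segment_crypts(ph$volumes$PAFhy, slice_interval = 13)
  cells <- detect_neutrophils(ph$volumes$PAFhy, lm)
  expect_equal(nrow(cells), 0)
})

test_that("an all-background volume yields zero detections", {
  vol <- voxel_volume(array(0.01, c(40, 40, 40)), 2)
  expect_equal(nrow(detect_neutrophils(vol, intensity_threshold = 0.5)), 0)
})

test_that("abscess continuity keeps lumen-connected cells and drops detached ones", {
  sp <- crypt_spec(1, 120, 120, depth = 220, tube_radius = 45,
                   lumen_fraction = 0.6, goblet_density = 0)
  infl <- inflammation_spec(1, "abscess", neutrophil_count = 4, abscess_fill = 0.3)
  ph <- rasterize_specimen(sp, infl, shape = c(120, 120, 120), voxel_size = 2,
                           seed = 10)
  # five detached stromal cells, far from the crypt
  arr <- ph$volumes$PAFhy$intensities
  stroma <- list(c(30, 30, 60), c(200, 40, 100), c(40, 200, 150),
                 c(210, 210, 60), c(30, 210, 180))
  for (p in stroma) arr <- paint_sphere(arr, rep(2, 3), p, 5, 0.95)
  vol <- voxel_volume(arr, 2)
  lm <- segment_crypts(vol, slice_interval = 13)
  cells <- detect_neutrophils(vol, lm)
  kept <- restrict_to_abscess(cells, vol, lm, 1)
  expect_gt(nrow(cells), nrow(kept))          # stromal cells detected...
  expect_gte(nrow(kept), 1)                   # ...but only lumen-linked kept
  expect_true(all(kept$cell_id %in% cells$cell_id))
  # every kept centroid lies inside the crypt footprint; stromal ones do not
  expect_true(all(sqrt((kept$x_um - 120)^2 + (kept$y_um - 120)^2) < 45))
  expect_error(restrict_to_abscess(cells, vol, lm, 99), "unknown crypt_id")
})

test_that("a thin bridge through a wall breach links a cell to the lumen", {
  # synthetic label map: an ideal tube (membrane band 24-30 um radius,
  # lumen inside) with a breach carved through the wall at z = 60 um
  dims <- c(80, 80, 60); vx <- rep(2, 3)
  ctr <- c(80, 80)
  xs <- (seq_len(dims[1]) - 0.5) * 2 - ctr[1]
  ys <- (seq_len(dims[2]) - 0.5) * 2 - ctr[2]
  rad <- sqrt(outer(xs^2, ys^2, `+`))
  band <- rad >= 24 & rad <= 30
  inner <- rad < 24
  breach <- band & outer(xs, ys, function(a, b) abs(b) < 5 & a > 0)
  labels <- array(0L, dims); lumen <- array(0L, dims)
  arr <- array(0.02, dims)
  for (k in seq_len(dims[3])) {
    z <- (k - 0.5) * 2
    wall_k <- band & !(breach & abs(z - 60) <= 6)
    sl_lab <- matrix(0L, dims[1], dims[2]); sl_lab[wall_k] <- 1L
    sl_lum <- matrix(0L, dims[1], dims[2]); sl_lum[inner] <- 1L
    labels[, , k] <- sl_lab
    lumen[, , k] <- sl_lum
    sl <- arr[, , k]; sl[wall_k] <- 0.9; arr[, , k] <- sl
  }
  lm <- structure(
    list(labels = labels, lumen_labels = lumen, voxel_size = vx,
         slice_interval = 13, thresholds = c(`1` = 0.4)),
    class = "crypt_label_map"
  )
  # one cell inside the lumen, one outside near the breach, one far stromal
  arr <- paint_sphere(arr, vx, c(80, 80, 30), 5, 0.95)
  arr <- paint_sphere(arr, vx, c(122, 80, 60), 5, 0.95)
  arr <- paint_sphere(arr, vx, c(24, 24, 30), 5, 0.95)
  with_bridge <- arr
  for (x in seq(100, 116, by = 2)) {
    with_bridge <- paint_sphere(with_bridge, vx, c(x, 80, 60), 2.2, 0.95)
  }
  volb <- voxel_volume(with_bridge, 2)
  cells <- detect_neutrophils(volb, lm, intensity_threshold = 0.5)
  kept <- restrict_to_abscess(cells, volb, lm, 1)
  expect_true(all(kept$cell_id %in% cells$cell_id))
  expect_true(any(kept$x_um > 100))            # bridged outside cell retained
  expect_true(any(kept$x_um < 90))             # intra-lumen cell retained
  expect_false(any(kept$x_um < 40))            # far stromal cell dropped

  voln <- voxel_volume(arr, 2)
  cells2 <- detect_neutrophils(voln, lm, intensity_threshold = 0.5)
  kept2 <- restrict_to_abscess(cells2, voln, lm, 1)
  expect_false(any(kept2$x_um > 100))          # no bridge: outside cell dropped
  expect_true(any(cells2$x_um > 100))          # ...though still detected
})

test_that("depth distribution recovers placement bias and the uniform null", {
  cs <- cryptitis_case(seed = 44, count = 30, bias = 0.8)
  cells <- detect_neutrophils(cs$ph$volumes$PAFhy, cs$lm)
  zr <- range((clip_to_depth(cs$lm, 1)[, 3] - 0.5) * cs$lm$voxel_size[3])
  frac <- depth_distribution(cells, zr)
  expect_lt(abs(frac - 0.8), 0.15)

  # uniform-in-depth synthetic placement: close to 1/3 in the bottom third
  set.seed(5)
  fake <- tibble::tibble(z_um = runif(600, 0, 240))
  expect_lt(abs(depth_distribution(fake, c(0, 240)) - 1 / 3), 0.06)
  expect_equal(depth_distribution(tibble::tibble(z_um = c(230, 235)), c(0, 240)), 1)
  expect_error(depth_distribution(fake[0, ], c(0, 240)), "no cells")
})
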