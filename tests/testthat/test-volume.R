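test_that("HU windowing clamps into the window and preserves grid metadata", {
  a <- array(c(-12, 200, 75, 0, 150, 149.5), dim = c(6, 1, 1))
  v <- vol_img(a, spacing = c(1, 2, 3))
  w <- window_hu(v)
  expect_equal(as.vector(w$data), c(0, 150, 75, 0, 150, 149.5))
  expect_identical(w$spacing, v$spacing)
  # identity on in-range volumes
  v2 <- vol_img(array(runif(24, 0, 150), dim = c(2, 3, 4)))
  expect_identical(window_hu(v2)$data, v2$data)
  # constant volume unchanged, sum preserved
  v3 <- vol_img(array(75, dim = c(3, 3, 3)))
  expect_equal(sum(window_hu(v3)$data), sum(v3$data))
  expect_error(window_hu(v, lo = 10, hi = 10), "lo < hi")
})

test_that("masking and mirroring standardize lesions to the right hemisphere", {
  set.seed(11)
  shape <- c(21, 12, 12)
  mid <- 10  # 0-based midsagittal plane
  les <- array(0, dim = shape)
  les[4:7, 5:8, 5:8] <- runif(64, 40, 80)
  msk <- array(0, dim = shape)
  msk[4:7, 5:8, 5:8] <- 1
  v <- vol_img(les + 5)  # background intensity to be masked away
  m <- seg_mask(msk)
  out <- mask_and_mirror(v, m, mid)
  expect_true(out$mirrored)
  # brute-force reflection oracle: voxel (i) -> (2*mid - i), 0-based
  masked <- (les + 5) * msk
  oracle <- array(0, dim = shape)
  for (i in seq_len(shape[1])) {
    src <- 2 * mid - (i - 1) + 1
    if (src >= 1 && src <= shape[1]) oracle[i, , ] <- masked[src, , ]
  }
  expect_equal(out$image$data, oracle)
  # mirrored lesion now sits right of the plane -> no further flip
  out2 <- mask_and_mirror(out$image, out$mask, mid)
  expect_false(out2$mirrored)
  # reflection is an involution
  back <- tbmorph:::reflect_x(out$image$data, mid)
  expect_identical(back, masked)
  # right-sided lesion: masked but untouched
  rshift <- mask_and_mirror(out$image, out$mask, 3)
  expect_false(rshift$mirrored)
  # symmetric lesion about the plane: center of mass on it, no flip
  sym <- array(0, dim = shape)
  sym[9:13, 5:8, 5:8] <- 1
  outs <- mask_and_mirror(vol_img(sym * 50), seg_mask(sym), mid)
  expect_false(outs$mirrored)
  expect_error(mask_and_mirror(v, seg_mask(array(0, shape)), mid), "empty")
})

test_that("curvature flow fixes flat regions and erodes impulses", {
  v <- vol_img(array(42, dim = c(10, 10, 10)))
  expect_equal(smooth_curvature(v)$data, v$data, tolerance = 1e-12)
  expect_identical(smooth_curvature(v, n_steps = 0), v)
  # single-voxel impulse: peak strictly decreases at every step
  imp <- array(0, dim = c(9, 9, 9)); imp[5, 5, 5] <- 100
  vi <- vol_img(imp)
  peaks <- numeric(4)
  cur <- vi
  for (k in 1:4) {
    cur <- smooth_curvature(cur, n_steps = 1)
    peaks[k] <- max(cur$data)
  }
  expect_true(all(diff(c(100, peaks)) < 0))
  # ball interior: values away from the boundary unchanged within 1e-6
  # (information travels one voxel per step, so keep the core clear of the
  # boundary by more than n_steps voxels; study-resolution 1 mm grid)
  ph <- make_phantom(phantom_spec(radii = 22), make_grid(48, 1))
  sm <- smooth_curvature(ph$image)
  core <- make_phantom(phantom_spec(radii = 6), make_grid(48, 1))$mask$data > 0
  expect_lt(max(abs(sm$data[core] - ph$image$data[core])), 1e-6)
  # protocol mass drift below 1% at study resolution
  expect_lt(abs(sum(sm$data) - sum(ph$image$data)) / sum(ph$image$data), 0.01)
  expect_error(smooth_curvature(vi, step = -1), "non-negative")
})

test_that("mass normalization is exact, idempotent and scale invariant", {
  a <- array(runif(60, 0, 5), dim = c(5, 4, 3))
  v <- vol_img(a * 250 / sum(a))
  n1 <- normalize_mass(v)
  expect_equal(sum(n1$data), 1, tolerance = 1e-12)
  expect_identical(n1$units, "normalized-mass")
  expect_equal(n1$data, v$data / 250, tolerance = 1e-12)
  expect_equal(normalize_mass(n1)$data, n1$data, tolerance = 1e-12)
  v3 <- v; v3$data <- v$data * 3
  expect_equal(normalize_mass(v3)$data, n1$data, tolerance = 1e-12)
  expect_error(normalize_mass(vol_img(array(0, c(2, 2, 2)))), "zero")
})

test_that("lesion volume is voxel count times voxel volume, intensity free", {
  m <- seg_mask(array(rep(c(1, 0), 500), dim = c(10, 10, 10)))
  expect_equal(lesion_volume_mL(m), 0.5)
  cube <- seg_mask(array(1, dim = c(10, 10, 10)))
  expect_equal(lesion_volume_mL(cube), 1)
  # digitized ball oracle: within 3% of (4/3) pi r^3
  ball <- make_phantom(phantom_spec(radii = 10), make_grid(28, 1))
  expect_equal(lesion_volume_mL(ball$mask), 4 / 3 * pi * 1e3 / 1e3,
               tolerance = 0.03)
  # the study inclusion threshold arithmetic: 7000 voxels at 1 mm = 7 mL
  m7 <- seg_mask(array(c(rep(1, 7000), rep(0, 3^3 * 1000 - 7000)),
                       dim = c(30, 30, 30)))
  expect_equal(lesion_volume_mL(m7), 7)
})

test_that("growth rate is volume over minutes", {
  expect_equal(growth_rate(30, 100), 0.3)
  expect_equal(growth_rate(0, 55), 0)
  expect_equal(growth_rate(25, 60), 0.4167, tolerance = 1e-4)
  expect_error(growth_rate(10, 0), "positive")
})

test_that("windowing, masking and normalization are idempotent once applied", {
  ph <- make_phantom(phantom_spec(radii = c(13, 10, 9),
                                  heterogeneity_amp = 0.3, seed = 2),
                     make_grid(24, 2))
  once <- prep_phantom(ph)
  # re-windowing and re-normalizing a preprocessed image is the identity
  # (the diffusive smoother itself is deliberately not a projection)
  again <- normalize_mass(window_hu(vol_img(once$data, once$spacing,
                                            once$origin, units = "HU")))
  expect_lt(nmse(again, once), 1e-18)
  # masking is idempotent on a masked image (lesion already right of plane)
  mm <- mask_and_mirror(window_hu(ph$image), ph$mask, 5)
  mm2 <- mask_and_mirror(mm$image, mm$mask, 5)
  expect_identical(mm2$image$data, mm$image$data)
})

test_that("NIfTI round trip preserves data and spacing", {
  ph <- make_phantom(phantom_spec(radii = 10, heterogeneity_amp = 0.2,
                                  seed = 4), make_grid(20, 2))
  tmp <- tempfile(fileext = ".nii.gz")
  write_volume(ph$image, tmp)
  back <- read_volume(tmp)
  expect_equal(back$data, ph$image$data, tolerance = 1e-6)
  expect_equal(back$spacing, ph$image$spacing)
  tmpm <- tempfile(fileext = ".nii.gz")
  write_volume(ph$mask, tmpm)
  mm <- read_mask(tmpm)
  expect_identical(mm$data, ph$mask$data)
  unlink(c(tmp, tmpm))
})
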