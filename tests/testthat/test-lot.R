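# Core transport solver properties on small grids; the full-scale oracle
# suite (48^3 translate law, 10-phantom round trips) lives in
# test-acceptance.R.

cfg_fast <- solver_config(max_iters = 30, tol = 1e-7)

test_that("the C++ objective kernel matches the R reference and its own
           finite differences", {
  set.seed(7)
  d <- c(9, 8, 7)
  I0a <- array(runif(prod(d), 0.5, 1.5), d); I0a <- I0a / sum(I0a)
  I1a <- array(runif(prod(d), 0.5, 1.5), d); I1a <- I1a / sum(I1a)
  cfg <- solver_config(mp_penalty = 50, curl_penalty = 2,
                       smooth_penalty = 3, fold_penalty = 10,
                       det_min = 1, mass_penalty = 30)
  env <- list(I0a = I0a, I1a = I1a, cc = tbmorph:::coord_arrays(d),
              I0_ss = sum(I0a^2), cfg = cfg, attach = 1e-3 / prod(d))
  u <- lapply(1:3, function(i) array(rnorm(prod(d), 0, 0.3), d))
  a <- tbmorph:::mp_objective(u, env, want_grad = TRUE)
  b <- tbmorph:::mp_objective_ref(u, env, want_grad = TRUE)
  expect_equal(a$J, b$J, tolerance = 1e-12)
  for (i in 1:3) expect_lt(max(abs(a$grad[[i]] - b$grad[[i]])), 1e-12)
  expect_equal(a$mp_residual, b$mp_residual, tolerance = 1e-12)
  expect_equal(a$min_det, b$min_det, tolerance = 1e-12)
  # analytic gradient against central finite differences at interior voxels
  for (trial in 1:10) {
    comp <- sample(3, 1)
    idx <- sapply(d, function(n) sample(3:(n - 2), 1))
    h <- 1e-6
    up <- u; up[[comp]][idx[1], idx[2], idx[3]] <-
      up[[comp]][idx[1], idx[2], idx[3]] + h
    um <- u; um[[comp]][idx[1], idx[2], idx[3]] <-
      um[[comp]][idx[1], idx[2], idx[3]] - h
    num <- (tbmorph:::mp_objective(up, env)$J -
              tbmorph:::mp_objective(um, env)$J) / (2 * h)
    ana <- a$grad[[comp]][idx[1], idx[2], idx[3]]
    expect_equal(ana, num, tolerance = 1e-4)
  }
})

test_that("the identity problem yields a null map with zero cost", {
  g <- gauss_vol(20, c(10, 10, 10), 3)
  m <- solve_mp_map(g, g, cfg_fast)
  expect_lt(max(abs(m$u)), 0.05)
  expect_lt(m$transport_cost, 1e-6)
  expect_true(m$converged)
  expect_equal(wasserstein_distance(m), 0, tolerance = 1e-3)
})

test_that("solver rejects bad inputs", {
  g <- gauss_vol(16, c(8, 8, 8), 3)
  h <- gauss_vol(12, c(6, 6, 6), 3)
  expect_error(solve_mp_map(g, h), "same grid")
  raw <- vol_img(array(1, dim = c(16, 16, 16)))
  expect_error(solve_mp_map(g, raw), "normalized-mass")
  bad <- g; bad$data <- bad$data * 2
  expect_error(solve_mp_map(g, bad), "sum to 1")
})

test_that("solver is deterministic", {
  ph <- make_phantom(phantom_spec(radii = c(10, 8, 8), center = c(3, -2, 0),
                                  heterogeneity_amp = 0.3, seed = 6),
                     make_grid(20, 2.5))
  I1 <- prep_phantom(ph)
  I0 <- prep_phantom(make_phantom(phantom_spec(radii = 9),
                                  make_grid(20, 2.5)))
  m1 <- solve_mp_map(I0, I1, cfg_fast)
  m2 <- solve_mp_map(I0, I1, cfg_fast)
  expect_identical(m1$u, m2$u)
  expect_identical(m1$transport_cost, m2$transport_cost)
})

test_that("separable problems reduce to 1D CDF rearrangement per axis", {
  n <- c(28, 16, 16)
  px0 <- dnorm(seq_len(n[1]), 11.5, 2.5)
  px1 <- 0.6 * dnorm(seq_len(n[1]), 14, 2.2) +
    0.4 * dnorm(seq_len(n[1]), 16.5, 2.6)
  py <- dnorm(seq_len(n[2]), 8.5, 2.2)
  pz <- dnorm(seq_len(n[3]), 8, 2.8)
  I0 <- separable_vol(px0, py, pz)
  I1 <- separable_vol(px1, py, pz)
  m <- solve_mp_map(I0, I1, solver_config(max_iters = 60, tol = 1e-7),
                    crop = FALSE)
  oracle_x <- cdf_rearrange_oracle(px0, px1)
  ux_oracle <- array(rep(oracle_x - seq_len(n[1]), times = n[2] * n[3]),
                     dim = n)
  err <- m$u[, , , 1] - ux_oracle
  expect_lt(wrms(err, I0$data), 0.1)
  # y and z axes stay near identity (looser: transverse wobble of the
  # discrete optimum is not part of the 1D oracle)
  expect_lt(wrms(m$u[, , , 2], I0$data), 0.15)
  expect_lt(wrms(m$u[, , , 3], I0$data), 0.15)
})

test_that("translate distances scale linearly (LOT embedding linearity)", {
  sh <- 32
  I0 <- gauss_vol(sh, c(12, 16, 16), 3)
  I1 <- gauss_vol(sh, c(15, 16, 16), 3)   # d1 = 3
  I2 <- gauss_vol(sh, c(18, 16, 16), 3)   # d2 = 6
  m1 <- solve_mp_map(I0, I1, cfg_fast)
  m2 <- solve_mp_map(I0, I2, cfg_fast)
  w1 <- wasserstein_distance(m1)
  w2 <- wasserstein_distance(m2)
  expect_equal(w2 / w1, 2, tolerance = 0.1)
  e0 <- lot_embed(solve_mp_map(I0, I0, cfg_fast))
  e1 <- lot_embed(m1)
  e2 <- lot_embed(m2)
  d01 <- lot_distance(e0, e1)
  d02 <- lot_distance(e0, e2)
  d12 <- lot_distance(e1, e2)
  # distances between translates approximate the translation distances
  expect_equal(d02 / d01, 2, tolerance = 0.1)
  expect_equal(d12 / d01, 1, tolerance = 0.1)
})

test_that("embeddings flatten losslessly and form a metric", {
  I0 <- gauss_vol(16, c(8, 8, 8), 2.5)
  I1 <- gauss_vol(16, c(10, 9, 8), 2.5)
  m <- solve_mp_map(I0, I1, cfg_fast)
  e <- lot_embed(m)
  expect_length(as.numeric(e), 3 * prod(m$shape))
  # flatten -> unflatten round trip is bit exact
  expect_identical(tbmorph:::embedding_field(e), -m$u)
  # identity map embeds to the zero vector
  e0 <- lot_embed(solve_mp_map(I0, I0, cfg_fast))
  expect_equal(max(abs(as.numeric(e0))), 0, tolerance = 0.05)
  # metric axioms
  expect_identical(lot_distance(e, e), 0)
  expect_identical(lot_distance(e, e0), lot_distance(e0, e))
  I2 <- gauss_vol(16, c(7, 8, 9), 2.5)
  e2 <- lot_embed(solve_mp_map(I0, I2, cfg_fast))
  expect_lte(lot_distance(e, e2),
             lot_distance(e, e0) + lot_distance(e0, e2) + 1e-12)
  # grid/reference mismatch is refused
  I3 <- gauss_vol(12, c(6, 6, 6), 2)
  e3 <- lot_embed(solve_mp_map(I3, I3, cfg_fast))
  expect_error(lot_distance(e, e3), "reference")
})

test_that("mass is conserved under the solved map", {
  set.seed(9)
  ph <- make_phantom(phantom_spec(radii = c(11, 9, 8), center = c(2, 3, -2),
                                  heterogeneity_amp = 0.3, seed = 12),
                     make_grid(24, 2))
  I1 <- prep_phantom(ph)
  ph0 <- make_phantom(phantom_spec(radii = 10), make_grid(24, 2))
  I0 <- prep_phantom(ph0)
  m <- solve_mp_map(I0, I1, solver_config(max_iters = 40))
  u <- list(array(m$u[, , , 1], m$shape), array(m$u[, , , 2], m$shape),
            array(m$u[, , , 3], m$shape))
  M <- tbmorph:::jac_entries(u)
  det <- tbmorph:::jac_det(M)
  cc <- tbmorph:::coord_arrays(m$shape)
  W <- array(tbmorph:::interp3(I1$data, cc$x + u[[1]], cc$y + u[[2]],
                               cc$z + u[[3]]), m$shape)
  pushed <- sum(det * W)
  expect_lt(abs(pushed - sum(I0$data)) / sum(I0$data), 1e-3)
  # and the admissibility condition holds on the numerical support
  supp <- I0$data > max(I0$data) * 1e-3
  expect_gt(min(det[supp]), 0)
})

test_that("generative inversion honours its sign convention", {
  I0 <- prep_phantom(make_phantom(phantom_spec(radii = c(12, 10, 9),
                                               heterogeneity_amp = 0.2,
                                               seed = 3),
                                  make_grid(24, 2)))
  z <- array(0, dim = c(24, 24, 24, 3))
  # zero field reproduces the reference exactly
  expect_lt(nmse(invert_embedding(z, I0), I0), 1e-18)
  # constant field d: f_v = x - v, so the image translates by -d
  d <- z; d[, , , 1] <- 2
  tr <- invert_embedding(d, I0)
  shifted <- array(0, dim = c(24, 24, 24))
  shifted[1:22, , ] <- I0$data[3:24, , ]
  expect_lt(nmse(tr, vol_img(shifted, I0$spacing, I0$origin,
                             units = "normalized-mass")), 1e-6)
  # a folding field on the support is refused with a located error
  bad <- z
  bad[, , , 1] <- 3 * sin(2 * pi * tbmorph:::coord_arrays(c(24, 24, 24))$x / 4)
  expect_error(invert_embedding(bad, I0), "not invertible")
})

test_that("solved maps invert back to the target image", {
  I0 <- prep_phantom(make_phantom(phantom_spec(radii = 11), make_grid(24, 2)))
  I1 <- prep_phantom(make_phantom(phantom_spec(radii = c(12, 9, 10),
                                               center = c(3, -3, 2),
                                               heterogeneity_amp = 0.3,
                                               seed = 8),
                                  make_grid(24, 2)))
  m <- solve_mp_map(I0, I1, solver_config(max_iters = 60))
  rec <- invert_embedding(m, I0)
  expect_lt(nmse(rec, I1), 0.05)
  # embedding vector and map agree through the inversion
  rec2 <- invert_embedding(lot_embed(m), I0)
  expect_lt(nmse(rec2, rec), 1e-18)
})
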