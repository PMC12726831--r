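test_that("phantom construction realizes the requested morphology", {
  g <- make_grid(48, 1)
  # uniform ellipsoid: zero in-mask coefficient of variation
  u <- make_phantom(phantom_spec(radii = c(14, 10, 8), shell_ratio = 1,
                                 heterogeneity_amp = 0), g)
  expect_equal(density_heterogeneity(u$image, u$mask), 0, tolerance = 1e-12)
  # equal radii: eccentricity ~ 0 within voxelization tolerance
  s <- make_phantom(phantom_spec(radii = 10), g)
  expect_lt(shape_eccentricity(s$mask), 0.05)
  # constructed shell ratio 2 recovered by direct voxel averaging
  sh <- make_phantom(phantom_spec(radii = 12, shell_ratio = 2,
                                  shell_frac = 0.25), g)
  expect_equal(peripheral_density_ratio(sh$image, sh$mask), 2,
               tolerance = 0.05)
  # mask volume close to the analytic ellipsoid volume at >= 8 voxels/radius
  e <- make_phantom(phantom_spec(radii = c(14, 10, 8)), g)
  expect_equal(lesion_volume_mL(e$mask), 4 / 3 * pi * 14 * 10 * 8 / 1000,
               tolerance = 0.05)
  # normalized phantom carries unit mass
  expect_equal(sum(normalize_mass(e$image)$data), 1, tolerance = 1e-12)
  # reproducibility of the texture
  t1 <- make_phantom(phantom_spec(radii = 10, heterogeneity_amp = 0.4,
                                  seed = 9), g)
  t2 <- make_phantom(phantom_spec(radii = 10, heterogeneity_amp = 0.4,
                                  seed = 9), g)
  expect_identical(t1$image$data, t2$image$data)
  expect_error(make_phantom(phantom_spec(radii = 60), g), "fit")
})

test_that("expansion label thresholds growth at 6 mL inclusively", {
  expect_true(expansion_label(6.0))
  expect_false(expansion_label(5.999))
  expect_false(expansion_label(-2))
  expect_equal(expansion_label(c(7, 3)), c(TRUE, FALSE))
  expect_error(expansion_label(NaN), "finite")
})

test_that("cohorts are reproducible and reach the target prevalence", {
  g <- make_grid(24, 3)
  cs <- cohort_spec(n = 12, grid = g, effect_weights = c(size = 4),
                    noise_sd = 2, seed = 21)
  c1 <- make_cohort(cs)
  c2 <- make_cohort(cs)
  expect_identical(c1[[5]]$image$data, c2[[5]]$image$data)
  expect_identical(c1[[5]]$growth_mL, c2[[5]]$growth_mL)
  # cohorts are order-independent: per-subject streams are private
  expect_identical(c1[[3]]$growth_mL, make_cohort(cs)[[3]]$growth_mL)
  # null-effect prevalence lands inside the binomial 95% CI of the target
  csn <- cohort_spec(n = 1000, grid = make_grid(16, 4),
                     effect_weights = c(size = 0), noise_sd = 2,
                     target_prevalence = 0.33, seed = 8)
  cn <- make_cohort(csn)
  prev <- mean(vapply(cn, `[[`, TRUE, "expansion"))
  expect_lt(abs(prev - 0.33), 1.96 * sqrt(0.33 * 0.67 / 1000) + 0.03)
})

test_that("noiseless size-only outcomes are separable by lesion volume", {
  cs <- cohort_spec(n = 30, grid = make_grid(40, 3),
                    effect_weights = c(size = 4), noise_sd = 0, seed = 31)
  coh <- make_cohort(cs)
  vols <- vapply(coh, function(r) lesion_volume_mL(r$mask), 0)
  labs <- vapply(coh, `[[`, TRUE, "expansion")
  expect_true(length(unique(labs)) == 2)
  expect_equal(univariate_auroc(vols, labs), 1)
})

test_that("increasing the size effect increases expected growth", {
  cs0 <- cohort_spec(n = 200, grid = make_grid(16, 4),
                     effect_weights = c(size = 0), intercept = 4,
                     noise_sd = 0, seed = 13)
  cs1 <- cohort_spec(n = 200, grid = make_grid(16, 4),
                     effect_weights = c(size = 4), intercept = 4,
                     noise_sd = 0, seed = 13)
  # paired draws: same per-subject streams, only the weight changes
  g0 <- vapply(make_cohort(cs0), `[[`, 0, "growth_mL")
  g1 <- vapply(make_cohort(cs1), `[[`, 0, "growth_mL")
  z <- vapply(make_cohort(cs1), function(r) r$factors[["size"]], 0)
  expect_gt(cor(g1 - g0, z), 0.99)
  expect_gt(mean(g1[z > 0]), mean(g0[z > 0]))
})

test_that("cohort round trips through NIfTI + CSV manifest", {
  cs <- cohort_spec(n = 4, grid = make_grid(20, 2.5),
                    effect_weights = c(size = 4), seed = 3)
  coh <- make_cohort(cs)
  dir <- tempfile("cohort_")
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_cohort(dir)
  expect_equal(length(back), 4)
  expect_equal(back[[2]]$image$data, coh[[2]]$image$data, tolerance = 1e-6)
  expect_equal(back[[2]]$growth_mL, coh[[2]]$growth_mL, tolerance = 1e-6)
  expect_identical(back[[2]]$expansion, coh[[2]]$expansion)
  expect_equal(back[[2]]$covariates[["age"]], coh[[2]]$covariates[["age"]],
               tolerance = 1e-6)
  unlink(dir, recursive = TRUE)
})
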