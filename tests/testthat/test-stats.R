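test_that("PCA recovers a planted low-rank subspace and honours var_frac", {
  set.seed(41)
  n <- 100; p <- 40
  B <- qr.Q(qr(matrix(rnorm(p * 3), p, 3)))      # planted orthonormal basis
  X <- matrix(rnorm(n * 3), n, 3) %*% t(B) * 4 +
    matrix(rnorm(n * p, sd = 0.04 * 4), n, p)    # 1% isotropic noise
  pca <- fit_pca(X, 0.95)
  expect_gte(pca$n_retained, 3)
  # principal angles between top-3 estimated and planted subspaces < 10 deg
  sv <- svd(t(B) %*% pca$rotation[, 1:3])$d
  expect_lt(max(acos(pmin(sv, 1))) * 180 / pi, 10)
  # components orthonormal
  R <- pca$rotation[, 1:pca$n_retained]
  expect_lt(max(abs(crossprod(R) - diag(pca$n_retained))), 1e-8)
  # identical rows are degenerate
  expect_error(fit_pca(matrix(1, 5, 4)), "zero variance")
  # var_frac = 1 retains the full rank and reconstructs exactly
  pf <- fit_pca(X, 1)
  expect_equal(pf$n_retained, min(n - 1, p))
  sc <- predict(pf, X)
  Xr <- pca_backproject(pf, sc)
  expect_lt(max(abs(Xr - X)), 1e-8)
})

test_that("pLDA approaches the mean-difference direction for large penalty", {
  set.seed(42)
  n <- 120
  X <- matrix(rnorm(n * 6), n, 6)
  X[, 2] <- X[, 2] * 3 + X[, 1]    # anisotropic within-class covariance
  y <- rep(c(TRUE, FALSE), each = n / 2)
  X[y, 1] <- X[y, 1] + 2
  X[y, 3] <- X[y, 3] + 1
  f <- fit_plda(X, y, lambda_grid = 1e8)
  md <- colMeans(X[y, ]) - colMeans(X[!y, ])
  md <- md / sqrt(sum(md^2))
  ang <- acos(min(abs(sum(f$direction * md)), 1)) * 180 / pi
  expect_lt(ang, 1)
  expect_equal(sqrt(sum(f$direction^2)), 1, tolerance = 1e-10)
})

test_that("pLDA threshold separates two projected Gaussians sensibly", {
  set.seed(43)
  X <- rbind(matrix(rnorm(200, 0), 100, 2), matrix(rnorm(200, 2), 100, 2))
  y <- rep(c(FALSE, TRUE), each = 100)
  f <- fit_plda(X, y)
  expect_true(f$threshold > f$proj_mean["no"] &&
                f$threshold < f$proj_mean["yes"])
  m <- classification_metrics(predict(f, X), y, f$threshold)
  expect_gt(m$auroc, 0.9)
  expect_error(fit_plda(X, rep(TRUE, 200)), "both classes")
})

test_that("single-outcome CCA is exact without noise and recovers beta", {
  set.seed(44)
  X <- matrix(rnorm(200 * 5), 200, 5)
  beta <- c(2, -1, 0.5, 0, 0)
  y0 <- drop(X %*% beta)
  f0 <- fit_cca(X, y0)
  expect_equal(f0$train_cor, 1, tolerance = 1e-8)
  expect_gt(abs(sum(f0$direction * beta / sqrt(sum(beta^2)))), 1 - 1e-6)
  expect_error(fit_cca(X, rep(2, 200)), "variance")
})

test_that("location vector and centering agree and invert cleanly", {
  g <- make_grid(32, 2)
  ph <- make_phantom(phantom_spec(center = c(6, -4, 2), radii = 9), g)
  ctr <- c(0, 0, 0)  # grid center in world mm
  lv <- location_vector(ph$mask, ctr)
  expect_equal(lv, c(6, -4, 2), tolerance = 1)
  li <- make_location_invariant(ph$image, ph$mask, ctr)
  expect_equal(li$translation, lv)
  expect_lt(max(abs(location_vector(li$mask, ctr))), 0.5 * 2)
  # centering an already-centered lesion is a no-op
  ph0 <- make_phantom(phantom_spec(radii = 9), g)
  li0 <- make_location_invariant(ph0$image, ph0$mask, ctr)
  expect_identical(li0$image$data, ph0$image$data)
  # round trip through the inverse integer shift restores the data
  back <- tbmorph:::shift_zero(li$image$data, round(lv / g$spacing))
  expect_identical(back, ph$image$data)
  # shifting off the grid is an error
  far <- make_phantom(phantom_spec(center = c(10, 0, 0), radii = 16), g)
  expect_error(make_location_invariant(far$image, far$mask, c(-40, 0, 0)),
               "clip")
})

test_that("augmented features standardize by training statistics only", {
  set.seed(45)
  sc <- matrix(rnorm(40 * 6, 5, 3), 40, 6)
  tr <- matrix(rnorm(40 * 3, 0, 4), 40, 3)
  cl <- matrix(rnorm(40 * 4, 60, 10), 40, 4)
  a <- augment_features(sc, tr, cl)
  expect_equal(dim(a$a), c(40, 6 + 3 + 4))
  expect_lt(max(abs(colMeans(a$a))), 1e-10)
  expect_equal(unname(apply(a$a, 2, sd)), rep(1, 13), tolerance = 1e-10)
  # a test row uses the training parameters, not its own statistics
  te <- augment_features(sc[1:2, ] + 100, tr[1:2, ], cl[1:2, ],
                         params = a$params)
  expect_gt(mean(te$a[, 1]), 5)
  cl_na <- cl; cl_na[3, 2] <- NA
  expect_error(augment_features(sc, tr, cl_na), "missing")
})

test_that("classification metrics match the confusion-table arithmetic", {
  # 10 TP, 5 FN, 20 TN, 5 FP
  labels <- c(rep(TRUE, 15), rep(FALSE, 25))
  scores <- c(rep(1, 10), rep(-1, 5), rep(-1, 20), rep(1, 5))
  m <- classification_metrics(scores, labels, 0)
  expect_equal(m$sensitivity, 10 / 15, tolerance = 1e-12)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$ppv, 10 / 15, tolerance = 1e-12)
  expect_equal(m$npv, 0.8)
  # perfect and anti-perfect ranking
  expect_equal(classification_metrics(labels * 1, labels, 0.5)$auroc, 1)
  expect_equal(classification_metrics(-labels * 1, labels, 0.5)$auroc, 0)
  # AUROC is invariant under strictly monotone transforms of the scores
  set.seed(46)
  s <- rnorm(80); l <- s + rnorm(80) > 0
  expect_identical(classification_metrics(s, l, 0)$auroc,
                   classification_metrics(exp(s), l, 0)$auroc)
  expect_error(classification_metrics(s, rep(TRUE, 80), 0), "both classes")
})

test_that("AUROC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(47)
  s <- rnorm(150)
  l <- (s + rnorm(150)) > 0.3
  ours <- classification_metrics(s, l, 0)$auroc
  ref <- as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("Fisher combination behaves at its boundary cases", {
  expect_equal(fisher_combine(rep(1, 5)), 1)
  expect_equal(fisher_combine(0.3), 0.3, tolerance = 1e-12)
  expect_equal(fisher_combine(0.03), 0.03, tolerance = 1e-12)
  expect_lt(fisher_combine(c(0.01, 0.02, 0.01)), 0.01)
  expect_error(fisher_combine(c(0.5, 0)), "in \\(0, 1\\]")
})

test_that("AUC power is calibrated at the null and consistent at large n", {
  expect_equal(auc_power(170, 0.25, 0.5), 0.05, tolerance = 0.01)
  expect_gt(auc_power(1e5, 0.25, 0.7), 0.999)
  expect_error(auc_power(170, 0, 0.7), "prevalence")
  expect_error(auc_power(170, 0.25, 0.3), "auc_alt")
  # closed form vs Monte-Carlo binormal at a mid-power operating point,
  # where the normal approximation is at its loosest
  po <- auc_power(80, 0.3, 0.65)
  mc <- auc_power_mc(80, 0.3, 0.65, reps = 4000, seed = 11)
  expect_lt(abs(po - mc), 0.05)
})

test_that("repeated splits are deterministic and score separable cohorts", {
  set.seed(48)
  n <- 60
  lab <- rep(c(TRUE, FALSE), c(20, 40))
  X <- cbind(lab * 5 + rnorm(n, sd = 0.1), matrix(rnorm(n * 8), n, 8))
  plan <- split_plan(3, 0.6, seed = 99)
  m1 <- run_repeated_splits(X, lab, plan, model = "plda")
  m2 <- run_repeated_splits(X, lab, plan, model = "plda")
  expect_identical(m1$per_repeat, m2$per_repeat)
  expect_equal(m1$summary$auroc[["mean"]], 1)
  # CI brackets the mean
  expect_true(m1$summary$auroc[["lo"]] <= m1$summary$auroc[["mean"]] &&
                m1$summary$auroc[["mean"]] <= m1$summary$auroc[["hi"]])
  # continuous outcome via CCA on the same structure
  y <- drop(X[, 1]) * 2 + rnorm(n, sd = 0.2)
  mc <- run_repeated_splits(X, y, plan, model = "cca")
  expect_gt(mc$summary$cc[["mean"]], 0.9)
})
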