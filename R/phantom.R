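#' Regular grid specification for phantoms
#'
#' By default the origin is chosen so that world coordinate (0,0,0) mm sits at
#' the grid center, which is also where phantom cohorts place the template.
#'
#' @param shape integer length-3 voxel counts.
#' @param spacing mm per voxel, length 3 (or scalar, recycled).
#' @param origin world mm of voxel (0,0,0); default centers the grid on 0.
#' @return A list of class `tbm_grid`.
#' @export
make_grid <- function(shape = c(32, 32, 32), spacing = 2, origin = NULL) {
  shape <- as.integer(rep(shape, length.out = 3))
  spacing <- as.numeric(rep(spacing, length.out = 3))
  if (is.null(origin)) origin <- -(shape - 1) * spacing / 2
  structure(list(shape = shape, spacing = spacing, origin = as.numeric(origin)),
            class = "tbm_grid")
}

#' Ellipsoidal lesion phantom specification
#'
#' Phantoms are rotated ellipsoids with a two-compartment radial density (core
#' vs peripheral shell) multiplied by a positive, smoothed random texture
#' field. They emulate the lesion traits a transport-space model should pick
#' up: overall size (radii), shape eccentricity (anisotropic radii), density
#' heterogeneity (texture amplitude), and peripheral density distribution
#' (shell/core ratio).
#'
#' @param center world mm of the lesion center.
#' @param radii principal semi-axes (mm), length 3 (scalar recycled).
#' @param orientation Euler angles (radians), rotations about z, y, x.
#' @param core_density core intensity (arbitrary HU-like units).
#' @param shell_ratio peripheral/core density ratio (>= 0).
#' @param shell_frac fraction of the normalized radius occupied by the shell,
#'   in `[0, 1)`.
#' @param heterogeneity_amp relative amplitude of the texture field (>= 0).
#' @param heterogeneity_scale correlation length of the texture (mm).
#' @param seed integer seed making the texture reproducible.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(center = c(0, 0, 0), radii = 12,
                         orientation = c(0, 0, 0), core_density = 60,
                         shell_ratio = 1, shell_frac = 0.25,
                         heterogeneity_amp = 0, heterogeneity_scale = 6,
                         seed = 1L) {
  radii <- rep(radii, length.out = 3)
  if (any(radii <= 0)) tb_stop("tb_invalid_parameter", "radii must be positive")
  if (shell_ratio < 0) tb_stop("tb_invalid_parameter", "shell_ratio must be >= 0")
  if (shell_frac < 0 || shell_frac >= 1)
    tb_stop("tb_invalid_parameter", "shell_frac must be in [0, 1)")
  if (heterogeneity_amp < 0)
    tb_stop("tb_invalid_parameter", "heterogeneity_amp must be >= 0")
  structure(list(center = center, radii = radii, orientation = orientation,
                 core_density = core_density, shell_ratio = shell_ratio,
                 shell_frac = shell_frac, heterogeneity_amp = heterogeneity_amp,
                 heterogeneity_scale = heterogeneity_scale,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

euler_rotation <- function(ang) {
  cz <- cos(ang[1]); sz <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cx <- cos(ang[3]); sx <- sin(ang[3])
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Rz %*% Ry %*% Rx
}

# Separable Gaussian smoothing (sigma in voxels per axis) with clamped edges.
gauss_smooth3 <- function(a, sigma) {
  sigma <- rep(sigma, length.out = 3)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    w <- exp(-0.5 * ((-r:r) / s)^2)
    w <- w / sum(w)
    acc <- a * w[r + 1]
    for (k in seq_len(r)) {
      acc <- acc + w[r + 1 + k] * shift_clamp(a, ax, k) +
        w[r + 1 - k] * shift_clamp(a, ax, -k)
    }
    a <- acc
  }
  a
}

#' Synthesize an ellipsoidal lesion phantom on a grid
#'
#' @param spec a [phantom_spec()].
#' @param grid a [make_grid()] object.
#' @return A list with `image` ([vol_img()], HU-like units) and `mask`
#'   ([seg_mask()]).
#' @export
make_phantom <- function(spec, grid) {
  shape <- grid$shape; spacing <- grid$spacing; origin <- grid$origin
  lo <- origin
  hi <- origin + (shape - 1) * spacing
  rmax <- max(spec$radii)
  if (any(spec$center - rmax < lo) || any(spec$center + rmax > hi))
    tb_stop("tb_out_of_bounds", "ellipsoid does not fit inside the grid")
  cc <- coord_arrays(shape)
  wx <- origin[1] + (cc$x - 1) * spacing[1] - spec$center[1]
  wy <- origin[2] + (cc$y - 1) * spacing[2] - spec$center[2]
  wz <- origin[3] + (cc$z - 1) * spacing[3] - spec$center[3]
  R <- euler_rotation(spec$orientation)
  # body coordinates: b = R^T (x - c)
  bx <- R[1, 1] * wx + R[2, 1] * wy + R[3, 1] * wz
  by <- R[1, 2] * wx + R[2, 2] * wy + R[3, 2] * wz
  bz <- R[1, 3] * wx + R[2, 3] * wy + R[3, 3] * wz
  rho <- sqrt((bx / spec$radii[1])^2 + (by / spec$radii[2])^2 +
                (bz / spec$radii[3])^2)
  mask <- array(as.numeric(rho <= 1), dim = shape)
  if (sum(mask) == 0)
    tb_stop("tb_empty_lesion", "ellipsoid contains no voxel centers")
  dens <- array(spec$core_density, dim = shape)
  if (spec$shell_frac > 0)
    dens[rho > 1 - spec$shell_frac] <- spec$core_density * spec$shell_ratio
  if (spec$heterogeneity_amp > 0) {
    tex <- with_seed(spec$seed, {
      noise <- array(rnorm(prod(shape)), dim = shape)
      gauss_smooth3(noise, spec$heterogeneity_scale / spacing)
    })
    tex <- tex / max(sd(tex), 1e-12)
    dens <- dens * pmax(1 + spec$heterogeneity_amp * tex, 0.05)
  }
  img <- dens * mask
  list(image = vol_img(img, spacing = spacing, origin = origin, units = "HU"),
       mask = seg_mask(mask, spacing = spacing, origin = origin))
}

#' Hematoma expansion label
#'
#' Significant expansion is an increase of at least `threshold` mL between the
#' presentation and 24-hour scans; the boundary is inclusive.
#'
#' @param growth_mL absolute 24-hour volume change (mL).
#' @param threshold expansion threshold (mL), default 6.
#' @return Logical.
#' @export
expansion_label <- function(growth_mL, threshold = 6) {
  if (any(!is.finite(growth_mL)))
    tb_stop("tb_invalid_parameter", "growth must be finite")
  growth_mL >= threshold
}

#' Cohort simulation specification
#'
#' Latent morphological factors per subject (size, eccentricity,
#' heterogeneity, peripheral shell ratio, and a location projection) drive a
#' linear growth outcome; the expansion label thresholds growth at 6 mL.
#' Effect weights are in mL per standard deviation of each latent factor. The
#' intercept is tuned so the realized expansion prevalence matches
#' `target_prevalence`.
#'
#' @param n number of subjects (>= 2).
#' @param grid a [make_grid()] object.
#' @param effect_weights named numeric over
#'   `c("size","ecc","het","periph","loc")`, mL per factor SD; missing names
#'   default to 0.
#' @param intercept mL; `NULL` (default) auto-tunes to `target_prevalence`.
#' @param noise_sd residual growth noise SD (mL).
#' @param target_prevalence target expansion fraction in (0,1).
#' @param loc_direction unit vector defining the location effect projection.
#' @param seed master integer seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n, grid = make_grid(), effect_weights = c(size = 4),
                        intercept = NULL, noise_sd = 2,
                        target_prevalence = 0.33,
                        loc_direction = c(1, 0, 0), seed = 1L) {
  if (n < 2) tb_stop("tb_invalid_parameter", "cohort needs n >= 2")
  if (noise_sd < 0) tb_stop("tb_invalid_parameter", "noise_sd must be >= 0")
  if (target_prevalence <= 0 || target_prevalence >= 1)
    tb_stop("tb_invalid_parameter", "target_prevalence must be in (0,1)")
  w <- c(size = 0, ecc = 0, het = 0, periph = 0, loc = 0)
  if (length(effect_weights)) {
    bad <- setdiff(names(effect_weights), names(w))
    if (length(bad))
      tb_stop("tb_invalid_parameter",
              paste("unknown effect weight:", paste(bad, collapse = ", ")))
    if (any(!is.finite(effect_weights)))
      tb_stop("tb_invalid_parameter", "effect weights must be finite")
    w[names(effect_weights)] <- effect_weights
  }
  loc_direction <- loc_direction / sqrt(sum(loc_direction^2))
  structure(list(n = as.integer(n), grid = grid, effect_weights = w,
                 intercept = intercept, noise_sd = noise_sd,
                 target_prevalence = target_prevalence,
                 loc_direction = loc_direction, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Latent factor draws for one subject given its private seed. Returns raw
# phantom parameters plus standardized factor scores (z_*).
draw_factors <- function(seed, cs) {
  with_seed(seed, {
    r_base <- rlnorm(1, log(12), 0.3)
    # one-sided elongation (q >= 1, volume-neutral) so the latent maps
    # monotonically to measured shape eccentricity
    e_raw <- abs(rnorm(1, 0, 0.25))
    q <- exp(e_raw)
    shell_ratio <- runif(1, 0.8, 2.0)
    het_amp <- runif(1, 0, 0.5)
    center <- rnorm(3, 0, 4)
    age <- rnorm(1, 64.1, 12.45)
    sex <- rbinom(1, 1, 0.376)
    inr <- rlnorm(1, log(1.09), 0.15)
    ivh <- rbinom(1, 12, 0.12)
    noise <- rnorm(1)
    list(
      r_base = r_base, q = q, shell_ratio = shell_ratio, het_amp = het_amp,
      center = center, noise = noise,
      covariates = c(age = age, sex = sex, inr = inr, ivh_score = ivh),
      # half-normal standardization for the one-sided eccentricity factor
      z = c(size = (log(r_base) - log(12)) / 0.3,
            ecc = (e_raw - 0.25 * sqrt(2 / pi)) /
              (0.25 * sqrt(1 - 2 / pi)),
            het = (het_amp - 0.25) / (0.5 / sqrt(12)),
            periph = (shell_ratio - 1.4) / (1.2 / sqrt(12)),
            loc = sum(center * cs$loc_direction) / 4)
    )
  })
}

# Growth linear predictor (without intercept) for a factor draw.
growth_lp <- function(fac, cs) {
  sum(cs$effect_weights * fac$z) + cs$noise_sd * fac$noise
}

tune_intercept <- function(cs, n_sim = 5000) {
  seeds <- with_seed(cs$seed + 1L, sample.int(.Machine$integer.max, n_sim))
  lp <- vapply(seeds, function(s) growth_lp(draw_factors(s, cs), cs), 0)
  # bisection on realized prevalence P(intercept + lp >= 6)
  lo <- 6 - max(lp) - 1; hi <- 6 - min(lp) + 1
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    prev <- mean(mid + lp >= 6)
    if (prev < cs$target_prevalence) lo <- mid else hi <- mid
  }
  mid <- (lo + hi) / 2
  if (abs(mean(mid + lp >= 6) - cs$target_prevalence) > 0.03)
    tb_stop("tb_tuning_failure",
            "could not attain target prevalence with the given weights")
  mid
}

#' Simulate a phantom cohort with outcomes
#'
#' Each subject gets latent factors (size, eccentricity, heterogeneity,
#' peripheral ratio, center location) from its own counter-derived random
#' stream, a phantom image synthesized from them, independent clinical
#' covariates (age, sex, INR, IVH score), a growth outcome
#' `intercept + beta . factors + noise`, and the 6 mL expansion label.
#'
#' @param cs a [cohort_spec()].
#' @return A list of class `tbm_cohort`; each element has `image`, `mask`,
#'   `covariates`, `growth_mL`, `expansion`, `factors` and `subject_id`.
#' @export
make_cohort <- function(cs) {
  stopifnot(inherits(cs, "cohort_spec"))
  intercept <- cs$intercept
  if (is.null(intercept)) intercept <- tune_intercept(cs)
  seeds <- with_seed(cs$seed, sample.int(.Machine$integer.max, cs$n))
  grid <- cs$grid
  # keep the ellipsoid inside the grid: cap radii to the usable half-extent
  half_ext <- min((grid$shape - 1) * grid$spacing) / 2
  recs <- lapply(seq_len(cs$n), function(k) {
    fac <- draw_factors(seeds[k], cs)
    radii <- fac$r_base * c(fac$q, 1 / sqrt(fac$q), 1 / sqrt(fac$q))
    cap <- (half_ext - max(abs(fac$center)) - max(grid$spacing)) / max(radii)
    if (cap < 1) radii <- radii * cap
    ph <- make_phantom(
      phantom_spec(center = fac$center, radii = radii,
                   core_density = 60, shell_ratio = fac$shell_ratio,
                   shell_frac = 0.25, heterogeneity_amp = fac$het_amp,
                   heterogeneity_scale = 6, seed = seeds[k] %% 1000000L),
      grid)
    growth <- intercept + growth_lp(fac, cs)
    list(subject_id = sprintf("S%03d", k), image = ph$image, mask = ph$mask,
         covariates = fac$covariates, growth_mL = growth,
         expansion = expansion_label(growth), factors = fac$z)
  })
  structure(recs, class = "tbm_cohort", grid = grid, intercept = intercept,
            spec = cs)
}

#' @export
print.tbm_cohort <- function(x, ...) {
  grid <- attr(x, "grid")
  cat(sprintf("<tbm_cohort> n = %d, grid %s @ %s mm, expansion prevalence %.2f\n",
              length(x), paste(grid$shape, collapse = "x"),
              paste(signif(grid$spacing, 3), collapse = "x"),
              mean(vapply(x, `[[`, TRUE, "expansion"))))
  invisible(x)
}

#' Write / read a cohort as NIfTI pairs plus a CSV manifest
#'
#' The manifest has columns `subject_id, age, sex, inr, ivh_score,
#' onset_to_ct_min, volume0_mL, volume24_mL` plus file paths; images and masks
#' are NIfTI.
#'
#' @param cohort a `tbm_cohort`.
#' @param dir output directory (created if needed).
#' @param onset_to_ct_min assumed onset-to-scan time (min) recorded in the
#'   manifest, recycled over subjects.
#' @return `write_cohort()` the manifest path, invisibly; `read_cohort()` a
#'   `tbm_cohort`.
#' @export
write_cohort <- function(cohort, dir, onset_to_ct_min = 120) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  onset <- rep(onset_to_ct_min, length.out = length(cohort))
  rows <- lapply(seq_along(cohort), function(k) {
    r <- cohort[[k]]
    ip <- file.path(dir, paste0(r$subject_id, "_img.nii.gz"))
    mp <- file.path(dir, paste0(r$subject_id, "_mask.nii.gz"))
    write_volume(r$image, ip)
    write_volume(r$mask, mp)
    v0 <- lesion_volume_mL(r$mask)
    data.frame(subject_id = r$subject_id, age = r$covariates[["age"]],
               sex = r$covariates[["sex"]], inr = r$covariates[["inr"]],
               ivh_score = r$covariates[["ivh_score"]],
               onset_to_ct_min = onset[k], volume0_mL = v0,
               volume24_mL = v0 + r$growth_mL,
               image = basename(ip), mask = basename(mp),
               origin_x = r$image$origin[1], origin_y = r$image$origin[2],
               origin_z = r$image$origin[3])
  })
  man <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  write.csv(man, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  man <- read.csv(file.path(dir, "manifest.csv"))
  recs <- lapply(seq_len(nrow(man)), function(k) {
    img <- read_volume(file.path(dir, man$image[k]))
    msk <- read_mask(file.path(dir, man$mask[k]))
    if (all(c("origin_x", "origin_y", "origin_z") %in% names(man))) {
      org <- c(man$origin_x[k], man$origin_y[k], man$origin_z[k])
      img$origin <- org
      msk$origin <- org
    }
    growth <- man$volume24_mL[k] - man$volume0_mL[k]
    list(subject_id = man$subject_id[k], image = img, mask = msk,
         covariates = c(age = man$age[k], sex = man$sex[k], inr = man$inr[k],
                        ivh_score = man$ivh_score[k]),
         growth_mL = growth, expansion = expansion_label(growth),
         factors = NULL)
  })
  grid <- make_grid(recs[[1]]$image$shape, recs[[1]]$image$spacing,
                    recs[[1]]$image$origin)
  structure(recs, class = "tbm_cohort", grid = grid, spec = NULL)
}
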