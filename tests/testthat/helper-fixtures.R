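# Shared fixture builders; everything is generated in code at test time.

# Isotropic 3D Gaussian as a normalized-mass volume (voxel coordinates).
gauss_vol <- function(shape, center, sigma, spacing = 1) {
  shape <- rep(shape, length.out = 3)
  cc <- tbmorph:::coord_arrays(shape)
  a <- exp(-((cc$x - center[1])^2 + (cc$y - center[2])^2 +
               (cc$z - center[3])^2) / (2 * sigma^2))
  vol_img(a / sum(a), spacing = rep(spacing, length.out = 3),
          units = "normalized-mass")
}

# Separable product density p_x (x) p_y (y) p_z (z), normalized.
separable_vol <- function(px, py, pz, spacing = 1) {
  a <- outer(outer(px, py), pz)
  vol_img(a / sum(a), spacing = rep(spacing, 3), units = "normalized-mass")
}

# Standard preprocessing used across OT tests: window, mask, smooth,
# normalize.
prep_phantom <- function(ph) {
  img <- window_hu(ph$image)
  img$data <- img$data * ph$mask$data
  normalize_mass(smooth_curvature(img))
}

# Independent 1D optimal transport oracle: monotone CDF rearrangement
# computed by linear interpolation of the quantile function on a fine grid.
cdf_rearrange_oracle <- function(p, q) {
  n <- length(p)
  p <- p / sum(p); q <- q / sum(q)
  Fp <- cumsum(p) - p / 2
  Fq <- cumsum(q) - q / 2
  stats::approx(Fq, seq_len(n), xout = Fp, rule = 2, ties = "ordered")$y
}

# Normalized mean squared error between two volumes.
nmse <- function(a, b) {
  da <- if (inherits(a, "vol_img")) a$data else a
  db <- if (inherits(b, "vol_img")) b$data else b
  sum((da - db)^2) / sum(db^2)
}

# Mass-weighted RMS of a displacement error field.
wrms <- function(err, w) sqrt(sum(w * err^2) / sum(w))
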