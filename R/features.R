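# Native-domain morphometric features: the four lesion traits a
# transport-space model is expected to rediscover, measured directly from
# windowed HU images so each can serve as a univariate predictor.

#' Density heterogeneity (coefficient of variation)
#'
#' SD of in-mask intensities divided by their mean.
#'
#' @param v a [vol_img()] (windowed HU).
#' @param m its [seg_mask()].
#' @return Unitless CV.
#' @export
density_heterogeneity <- function(v, m) {
  stopifnot_same_grid(v, m)
  vals <- v$data[m$data > 0]
  if (length(vals) < 2)
    tb_stop("tb_degenerate_data", "need >= 2 in-mask voxels")
  mu <- mean(vals)
  if (mu <= 0) tb_stop("tb_degenerate_data", "in-mask mean must be positive")
  sd(vals) / mu
}

#' Shape eccentricity from second central moments
#'
#' `1 - sqrt(lambda_min / lambda_max)` of the mask's second-central-moment
#' tensor eigenvalues: 0 for a sphere, approaching 1 for elongated or
#' flattened shapes. Rotation invariant.
#'
#' @param m a [seg_mask()].
#' @return Eccentricity in `[0, 1)`.
#' @export
shape_eccentricity <- function(m) {
  idx <- which(m$data > 0)
  if (!length(idx)) tb_stop("tb_empty_lesion", "mask is empty")
  d <- m$shape
  ai <- arrayInd(idx, d)
  xyz <- sweep(ai, 2, m$spacing, `*`)
  ctr <- colMeans(xyz)
  xc <- sweep(xyz, 2, ctr)
  S <- crossprod(xc) / nrow(xc)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (ev[1] <= 0) return(1 - 1e-6)
  if (min(ev) <= 0) {
    warning("degenerate (coplanar) mask; eccentricity capped")
    return(1 - 1e-6)
  }
  1 - sqrt(min(ev) / max(ev))
}

# Interior depth by iterative 6-connected erosion: depth d means the voxel
# survives d erosions (1 = boundary layer). Integer chamfer-like transform
# adequate for quantile banding.
erosion_depth <- function(mask) {
  cur <- mask > 0
  depth <- array(0L, dim = dim(mask))
  d <- 0L
  while (any(cur)) {
    d <- d + 1L
    depth[cur] <- d
    nxt <- cur &
      shift_clamp(cur, 1, 1L) & shift_clamp(cur, 1, -1L) &
      shift_clamp(cur, 2, 1L) & shift_clamp(cur, 2, -1L) &
      shift_clamp(cur, 3, 1L) & shift_clamp(cur, 3, -1L)
    # border voxels have clamped neighbours; treat the grid edge as outside
    if (d > 1000L) break
    nxt[c(1, dim(mask)[1]), , ] <- FALSE
    nxt[, c(1, dim(mask)[2]), ] <- FALSE
    nxt[, , c(1, dim(mask)[3])] <- FALSE
    cur <- nxt
  }
  depth
}

#' Peripheral density ratio
#'
#' Mean intensity in the outer `shell_frac` band of the normalized interior
#' depth, divided by the mean intensity in the innermost `shell_frac` core.
#' Values above 1 indicate density concentrated at the lesion rim.
#' Invariant to intensity scaling.
#'
#' @param v a [vol_img()] (windowed HU).
#' @param m its [seg_mask()].
#' @param shell_frac band width as a fraction of the normalized depth.
#' @return Unitless ratio (>= 0).
#' @export
peripheral_density_ratio <- function(v, m, shell_frac = 0.25) {
  stopifnot_same_grid(v, m)
  dep <- erosion_depth(m$data)
  inside <- dep > 0
  if (!any(inside)) tb_stop("tb_empty_lesion", "mask is empty")
  dmax <- max(dep)
  # normalized boundary distance in (0, 1]: 1 at the rim, -> 0 at the core
  nd <- array(NA_real_, dim = dim(dep))
  nd[inside] <- (dep[inside] - 0.5) / dmax
  shell <- inside & nd <= shell_frac
  core <- inside & nd > 1 - shell_frac
  if (!any(shell) || !any(core))
    tb_stop("tb_degenerate_data", "mask too small to separate shell and core")
  denom <- mean(v$data[core])
  if (denom <= 0)
    tb_stop("tb_degenerate_data", "core has no density")
  mean(v$data[shell]) / denom
}

#' Univariate AUROC of a single feature
#'
#' @param feature numeric feature values.
#' @param labels logical outcome.
#' @return Rank-based AUROC.
#' @export
univariate_auroc <- function(feature, labels) {
  auroc_rank(feature, labels)
}

#' Morphometric feature table for a cohort
#'
#' Computes the four native-domain features (volume, density heterogeneity,
#' shape eccentricity, peripheral density ratio) per subject.
#'
#' @param cohort a `tbm_cohort` (see [make_cohort()] / [read_cohort()]).
#' @param shell_frac band width for [peripheral_density_ratio()].
#' @return data.frame keyed by `subject_id`, with outcome columns.
#' @export
feature_table <- function(cohort, shell_frac = 0.25) {
  rows <- lapply(cohort, function(r) {
    data.frame(
      subject_id = r$subject_id,
      volume_mL = lesion_volume_mL(r$mask),
      heterogeneity = density_heterogeneity(r$image, r$mask),
      eccentricity = shape_eccentricity(r$mask),
      peripheral_ratio = tryCatch(
        peripheral_density_ratio(r$image, r$mask, shell_frac),
        error = function(e) NA_real_),
      growth_mL = r$growth_mL,
      expansion = r$expansion)
  })
  do.call(rbind, rows)
}
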