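#' Volumetric image with grid metadata
#'
#' Container for a 3D scalar image on a regular grid. Voxel indices are
#' 0-based and voxel-centered; world coordinates are
#' `origin + index * spacing` (mm). Intensities are Hounsfield Units (`"HU"`)
#' or, after [normalize_mass()], a discrete probability measure
#' (`"normalized-mass"`).
#'
#' @param data 3D numeric array of finite, non-negative-capable intensities.
#' @param spacing numeric length-3, mm per voxel along each axis.
#' @param origin numeric length-3, world mm of voxel (0,0,0).
#' @param units `"HU"` or `"normalized-mass"`.
#' @return An object of class `vol_img`.
#' @export
vol_img <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                    units = c("HU", "normalized-mass")) {
  units <- match.arg(units)
  if (length(dim(data)) != 3L)
    tb_stop("tb_bad_grid", "image data must be a 3D array")
  if (!all(is.finite(data)))
    tb_stop("tb_bad_grid", "image intensities must all be finite")
  structure(
    list(data = data, shape = dim(data), spacing = as.numeric(spacing),
         origin = as.numeric(origin), units = units),
    class = "vol_img"
  )
}

#' @export
print.vol_img <- function(x, ...) {
  cat(sprintf("<vol_img> %s voxels, spacing %s mm, units %s, sum %.6g\n",
              paste(x$shape, collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              x$units, sum(x$data)))
  invisible(x)
}

#' Binary segmentation mask on the grid of its image
#'
#' @param data 3D array; values are rounded at 0.5 and must then be 0/1.
#' @param spacing,origin grid metadata, as in [vol_img()].
#' @return An object of class `seg_mask`.
#' @export
seg_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L)
    tb_stop("tb_bad_grid", "mask data must be a 3D array")
  b <- round(data)
  if (!all(b %in% c(0, 1)))
    tb_stop("tb_bad_mask", "mask is not binary after rounding at 0.5")
  structure(
    list(data = array(as.numeric(b), dim = dim(data)), shape = dim(data),
         spacing = as.numeric(spacing), origin = as.numeric(origin)),
    class = "seg_mask"
  )
}

#' @export
print.seg_mask <- function(x, ...) {
  cat(sprintf("<seg_mask> %s voxels, %d foreground, %.2f mL\n",
              paste(x$shape, collapse = "x"), sum(x$data > 0),
              sum(x$data > 0) * prod(x$spacing) / 1000))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stopifnot_same_grid <- function(a, b) {
  if (!same_grid(a, b))
    tb_stop("tb_grid_mismatch", "inputs are not defined on the same grid")
}

#' Read / write volumes and masks as NIfTI
#'
#' Spacing is taken from the NIfTI header (`pixdim`); masks are rounded at
#' 0.5 and validated as binary.
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @param units intensity units of the image being read.
#' @return `read_volume()` a [vol_img()]; `read_mask()` a [seg_mask()].
#' @export
read_volume <- function(path, units = "HU") {
  img <- RNifti::readNifti(path)
  sp <- attr(img, "pixdim")
  if (is.null(sp)) sp <- RNifti::pixdim(img)
  vol_img(array(as.numeric(img), dim = dim(img)[1:3]),
          spacing = sp[1:3], units = units)
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- attr(img, "pixdim")
  if (is.null(sp)) sp <- RNifti::pixdim(img)
  seg_mask(array(as.numeric(img), dim = dim(img)[1:3]), spacing = sp[1:3])
}

#' @rdname read_volume
#' @param v a [vol_img()] or [seg_mask()] to write.
#' @export
write_volume <- function(v, path) {
  img <- RNifti::asNifti(v$data, reference = NULL)
  RNifti::pixdim(img) <- v$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Clamp CT intensities into a Hounsfield window
#'
#' Values below `lo` are set to `lo`, values above `hi` to `hi` (clamping, not
#' deletion, so mask topology and total mass are preserved). The default
#' 0-150 HU window isolates blood-range densities.
#'
#' @param v a [vol_img()] in HU.
#' @param lo,hi window bounds in HU, `lo < hi`.
#' @return Windowed [vol_img()], grid metadata unchanged.
#' @export
window_hu <- function(v, lo = 0, hi = 150) {
  if (lo >= hi) tb_stop("tb_invalid_window", "window requires lo < hi")
  if (v$units != "HU") tb_stop("tb_bad_units", "window_hu expects an HU image")
  v$data <- pmin(pmax(v$data, lo), hi)
  v
}

#' Mask a lesion image and standardize it to one hemisphere
#'
#' Zeroes intensities outside the segmentation, then reflects image and mask
#' about the midsagittal voxel plane when the mask center of mass lies on the
#' left (x below `midsagittal_index`), so that all lesions end up in the right
#' hemisphere. A center of mass exactly on the plane is not flipped.
#'
#' @param v a [vol_img()].
#' @param m a [seg_mask()] on the same grid.
#' @param midsagittal_index 0-based voxel-x coordinate of the midsagittal
#'   plane (may be half-integer).
#' @return A list with elements `image`, `mask`, and logical `mirrored`.
#' @export
mask_and_mirror <- function(v, m, midsagittal_index) {
  stopifnot_same_grid(v, m)
  if (sum(m$data) == 0) tb_stop("tb_empty_lesion", "segmentation mask is empty")
  nx <- v$shape[1]
  if (midsagittal_index < 0 || midsagittal_index > nx - 1)
    tb_stop("tb_bad_grid", "midsagittal_index lies outside the grid")
  v$data <- v$data * m$data
  com_x0 <- com_voxel(m$data)[1] - 1  # 0-based
  mirrored <- com_x0 < midsagittal_index
  if (mirrored) {
    v$data <- reflect_x(v$data, midsagittal_index)
    m$data <- reflect_x(m$data, midsagittal_index)
  }
  list(image = v, mask = m, mirrored = mirrored)
}

# Reflect a 3D array about the midsagittal voxel plane x = mid (0-based,
# integer or half-integer). Nonzero voxels must stay on-grid; the operation is
# its own inverse on such arrays.
reflect_x <- function(a, mid) {
  nx <- dim(a)[1]
  src0 <- 2 * mid - (seq_len(nx) - 1)
  if (max(abs(src0 - round(src0))) > 1e-9)
    tb_stop("tb_bad_grid", "midsagittal_index must be integer or half-integer")
  src0 <- round(src0)
  keep <- src0 >= 0 & src0 <= nx - 1
  nz_x <- which(apply(a != 0, 1, any))
  if (!all(keep[nz_x]))
    tb_stop("tb_bad_grid", "reflection would move lesion voxels off the grid")
  out <- array(0, dim = dim(a))
  out[keep, , ] <- a[src0[keep] + 1L, , ]
  out
}

#' Curvature-driven smoothing of a lesion image
#'
#' Explicit-Euler iterations of curvature-driven flow,
#' `u <- u + step * (kappa |grad u| + diffusion * lap u)`: level-set mean
#' curvature motion (the standard finite-difference curvature formula,
#' replicated boundaries) blended with a weak Gaussian-type diffusion so
#' that isolated extrema, where the image gradient vanishes, are also
#' smoothed. Flat regions are exact fixed points. For `normalized-mass`
#' images the result is renormalized to unit mass.
#'
#' @param v a [vol_img()].
#' @param step time step per iteration (unitless), default 0.125.
#' @param n_steps number of iterations, default 5.
#' @param diffusion weight of the isotropic diffusion component relative to
#'   the curvature motion.
#' @return Smoothed [vol_img()].
#' @export
smooth_curvature <- function(v, step = 0.125, n_steps = 5, diffusion = 0.2) {
  if (step < 0) tb_stop("tb_invalid_parameter", "step must be non-negative")
  if (n_steps < 0) tb_stop("tb_invalid_parameter", "n_steps must be >= 0")
  if (n_steps == 0) return(v)
  u <- v$data
  eps <- 1e-12
  for (it in seq_len(n_steps)) {
    ux <- central_diff(u, 1); uy <- central_diff(u, 2); uz <- central_diff(u, 3)
    uxx <- shift_clamp(u, 1, 1) - 2 * u + shift_clamp(u, 1, -1)
    uyy <- shift_clamp(u, 2, 1) - 2 * u + shift_clamp(u, 2, -1)
    uzz <- shift_clamp(u, 3, 1) - 2 * u + shift_clamp(u, 3, -1)
    uxy <- central_diff(central_diff(u, 1), 2)
    uxz <- central_diff(central_diff(u, 1), 3)
    uyz <- central_diff(central_diff(u, 2), 3)
    g2 <- ux^2 + uy^2 + uz^2
    num <- uxx * (uy^2 + uz^2) + uyy * (ux^2 + uz^2) + uzz * (ux^2 + uy^2) -
      2 * (ux * uy * uxy + ux * uz * uxz + uy * uz * uyz)
    u <- u + step * (num / (g2 + eps) + diffusion * (uxx + uyy + uzz))
  }
  u[u < 0] <- 0
  v$data <- u
  if (v$units == "normalized-mass") {
    v$data <- v$data / sum(v$data)
  }
  v
}

#' Normalize an image to unit total mass
#'
#' Scales intensities so they sum to 1, after which the image is a discrete
#' probability measure suitable for optimal transport.
#'
#' @param v a [vol_img()] with positive total intensity.
#' @return A [vol_img()] with `units = "normalized-mass"`.
#' @export
normalize_mass <- function(v) {
  s <- sum(v$data)
  if (s <= 0) tb_stop("tb_zero_mass", "cannot normalize an all-zero volume")
  v$data <- v$data / s
  v$units <- "normalized-mass"
  v
}

#' Lesion volume in millilitres
#'
#' Number of foreground voxels times the voxel volume; depends only on the
#' mask, never on image intensities.
#'
#' @param m a [seg_mask()].
#' @return Volume in mL.
#' @export
lesion_volume_mL <- function(m) {
  n <- sum(m$data > 0)
  if (n == 0) tb_stop("tb_empty_lesion", "segmentation mask is empty")
  n * prod(m$spacing) / 1000
}

#' Hematoma growth rate at presentation
#'
#' Presentation volume divided by time from symptom onset to the first scan,
#' normalizing for inter-patient differences in time-to-imaging.
#'
#' @param v0_mL presentation volume (mL).
#' @param minutes_from_onset minutes from symptom onset to the scan (> 0).
#' @return Growth rate in mL/min.
#' @export
growth_rate <- function(v0_mL, minutes_from_onset) {
  if (minutes_from_onset <= 0)
    tb_stop("tb_invalid_time", "minutes_from_onset must be positive")
  v0_mL / minutes_from_onset
}
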