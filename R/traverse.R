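#' Traverse a fitted direction in transport space and synthesize images
#'
#' Moves along a model direction from the training mean,
#' `w(sigma) = mean + sigma * SD_proj * direction` (sigma in standard
#' deviations of the projected training data), maps each point back to an
#' embedding-space displacement field through the PCA (and, for augmented
#' models, the image block of the standardization), and inverts it against
#' the template with [invert_embedding()]. The sigma = 0 image is the
#' reconstruction of the training-mean embedding.
#'
#' @param fit a fitted [tbm()] model.
#' @param which `"plda"` (expansion direction) or `"cca"` (growth direction).
#' @param sigmas numeric traversal positions.
#' @return List with `images` (one [vol_img()] per sigma, `NULL` on
#'   inversion failure), `sigmas`, and `status` (per-sigma `"ok"` or the
#'   error message).
#' @export
traverse_direction <- function(fit, which = c("plda", "cca"),
                               sigmas = c(-2, -1, 0, 1, 2)) {
  which <- match.arg(which)
  model <- fit[[which]]
  if (is.null(model))
    tb_stop("tb_invalid_parameter", sprintf("model has no %s fit", which))
  if (any(!is.finite(sigmas)))
    tb_stop("tb_invalid_parameter", "sigmas must be finite")
  w <- model$direction
  A <- fit$feats
  proj <- drop(as.matrix(A) %*% w)
  sd_proj <- sd(proj)
  a_bar <- colMeans(as.matrix(A))
  k <- fit$pca$n_retained
  images <- vector("list", length(sigmas))
  status <- character(length(sigmas))
  for (i in seq_along(sigmas)) {
    pt <- a_bar + sigmas[i] * sd_proj * w
    s <- pt[seq_len(k)]
    if (!is.null(fit$aug_params)) {
      s <- s * fit$aug_params$sd[seq_len(k)] + fit$aug_params$mean[seq_len(k)]
    }
    v <- pca_backproject(fit$pca, s)
    field <- array(as.numeric(v), dim = c(fit$grid$shape, 3))
    # pull-back where the field is a diffeomorphism; fall back to the
    # conservative push-forward at extreme sigmas where it folds
    res <- tryCatch(
      list(img = invert_embedding(field, fit$template$image), st = "ok"),
      error = function(e) {
        img <- tryCatch(invert_embedding(field, fit$template$image,
                                         method = "pushforward"),
                        error = function(e2) NULL)
        list(img = img,
             st = if (is.null(img)) conditionMessage(e) else "pushforward")
      })
    images[[i]] <- res$img
    status[i] <- res$st
  }
  list(images = images, sigmas = sigmas, status = status)
}

# Map intensities in [0,1] through a "hot"-style colormap.
hot_map <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  r <- pmin(3 * x, 1)
  g <- pmin(pmax(3 * x - 1, 0), 1)
  b <- pmin(pmax(3 * x - 2, 0), 1)
  cbind(r, g, b)
}

#' Render a 2D overlay of a synthesized image on a background volume
#'
#' Grayscale background with a heat-colored, intensity-weighted overlay of
#' the synthesized image; deterministic for fixed inputs.
#'
#' @param template_ct background [vol_img()].
#' @param synthesized overlay [vol_img()] on the same grid.
#' @param plane `"axial"` (z slice), `"coronal"` (y) or `"sagittal"` (x).
#' @param slice_index 1-based slice index in the chosen plane.
#' @return List with `background` and `overlay` matrices and an `rgb` array
#'   (rows x cols x 3) ready for [graphics::rasterImage()].
#' @export
overlay_render <- function(template_ct, synthesized,
                           plane = c("axial", "coronal", "sagittal"),
                           slice_index) {
  stopifnot_same_grid(template_ct, synthesized)
  plane <- match.arg(plane)
  ax <- switch(plane, axial = 3L, coronal = 2L, sagittal = 1L)
  n <- template_ct$shape[ax]
  if (slice_index < 1 || slice_index > n)
    tb_stop("tb_out_of_bounds", "slice index outside the grid")
  slice_of <- function(a) {
    switch(plane,
      axial = a[, , slice_index],
      coronal = a[, slice_index, ],
      sagittal = a[slice_index, , ])
  }
  bg <- slice_of(template_ct$data)
  ov <- slice_of(synthesized$data)
  bmax <- max(template_ct$data)
  omax <- max(synthesized$data)
  bgn <- if (bmax > 0) bg / bmax else bg
  ovn <- if (omax > 0) ov / omax else ov
  alpha <- pmin(ovn * 2, 1)
  colr <- hot_map(as.vector(ovn))
  rgb_arr <- array(0, dim = c(nrow(bgn), ncol(bgn), 3))
  for (ch in 1:3) {
    rgb_arr[, , ch] <- (1 - alpha) * bgn +
      alpha * array(colr[, ch], dim = dim(bgn))
  }
  # raster orientation: rows top-to-bottom = decreasing second axis
  rgb_img <- aperm(rgb_arr[, ncol(bgn):1, , drop = FALSE], c(2, 1, 3))
  list(background = bgn, overlay = ovn, rgb = rgb_img)
}
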