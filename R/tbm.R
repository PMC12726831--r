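#' Fit a transport-based morphometry model to a lesion cohort
#'
#' End-to-end fitting: (1) preprocess every subject (HU windowing, masking,
#' optional hemisphere standardization, optional location centering,
#' curvature-driven smoothing, mass normalization); (2) estimate the
#' intrinsic mean template; (3) embed each subject by its mass-preserving
#' transport map to the template (LOT); (4) reduce with PCA; (5) fit the
#' penalized discriminant direction for the expansion label and/or the
#' most-correlated direction for continuous growth, optionally on features
#' augmented with the removed translation and clinical covariates.
#'
#' @param cohort a `tbm_cohort` (from [make_cohort()] or [read_cohort()]).
#' @param outcome which model(s) to fit: `"both"`, `"expansion"` (pLDA) or
#'   `"growth"` (CCA).
#' @param covariates `"none"` for the image-only model, `"location"` to add
#'   the translation coordinates, `"location+clinical"` to add the clinical
#'   vector (age, sex, INR, IVH score) as well.
#' @param var_frac PCA variance retention (default 0.95).
#' @param solver a [solver_config()] used for template and embeddings.
#' @param template_iters outer iterations of the intrinsic mean.
#' @param template_tol relative mean-cost tolerance of the intrinsic mean.
#' @param window HU window applied before masking.
#' @param smooth_step,smooth_steps curvature-flow smoothing parameters.
#' @param midsagittal optional 0-based voxel-x midsagittal plane; when given,
#'   lesions are mirrored into the right hemisphere before embedding.
#' @param location_invariant center each lesion at the template center
#'   before embedding (default: whenever covariates are used).
#' @param lambda_grid ridge grid for [fit_plda()].
#' @param verbose print stage progress.
#' @return An object of class `tbm`.
#' @seealso [predict.tbm()], [traverse_direction()], [run_repeated_splits()]
#' @export
tbm <- function(cohort, outcome = c("both", "expansion", "growth"),
                covariates = c("none", "location", "location+clinical"),
                var_frac = 0.95, solver = solver_config(max_iters = 30),
                template_iters = 3, template_tol = 1e-3,
                window = c(0, 150), smooth_step = 0.125, smooth_steps = 5,
                midsagittal = NULL,
                location_invariant = !identical(covariates[1], "none"),
                lambda_grid = 10^seq(-3, 3), verbose = FALSE) {
  outcome <- match.arg(outcome)
  covariates <- match.arg(covariates)
  grid <- attr(cohort, "grid")
  grid_center <- grid$origin + (grid$shape - 1) * grid$spacing / 2
  say <- function(...) if (verbose) message(sprintf(...))

  say("preprocessing %d subjects", length(cohort))
  prep <- lapply(cohort, function(r) {
    preprocess_record(r, window = window, smooth_step = smooth_step,
                      smooth_steps = smooth_steps, midsagittal = midsagittal,
                      center_at = if (location_invariant) grid_center)
  })
  images <- lapply(prep, `[[`, "image")
  translations <- do.call(rbind, lapply(prep, `[[`, "translation"))
  colnames(translations) <- c("tx", "ty", "tz")

  box <- support_box(images)
  say("template estimation (support box %s)",
      paste(vapply(box, function(b) paste(b, collapse = ":"), ""), collapse = " x "))
  tmpl <- intrinsic_mean(images, cfg = solver, max_outer = template_iters,
                         tol = template_tol, crop = box, verbose = verbose)

  say("embedding %d subjects", length(images))
  maps <- lapply(images, solve_mp_map, I0 = tmpl$image, cfg = solver,
                 crop = box)
  X <- do.call(rbind, lapply(maps, function(m) as.numeric(lot_embed(m))))

  pca <- fit_pca(X, var_frac)
  scores <- predict(pca, X)

  clin <- do.call(rbind, lapply(cohort, `[[`, "covariates"))
  covmat <- switch(covariates,
    "none" = NULL,
    "location" = translations,
    "location+clinical" = cbind(translations, clin))
  if (is.null(covmat)) {
    feats <- scores
    aug_params <- NULL
  } else {
    aug <- augment_features(scores, covmat[, 0, drop = FALSE], covmat)
    feats <- aug$a
    aug_params <- aug$params
  }

  labels <- vapply(cohort, `[[`, TRUE, "expansion")
  growth <- vapply(cohort, `[[`, 0, "growth_mL")
  plda <- NULL
  cca <- NULL
  if (outcome %in% c("both", "expansion")) {
    say("fitting pLDA (prevalence %.2f)", mean(labels))
    plda <- fit_plda(feats, labels, lambda_grid)
  }
  if (outcome %in% c("both", "growth")) {
    say("fitting CCA")
    cca <- fit_cca(feats, growth)
  }

  structure(list(
    template = tmpl, pca = pca, plda = plda, cca = cca,
    embeddings = X, scores = scores, feats = feats,
    aug_params = aug_params, covariates = covariates,
    covmat = covmat, labels = labels, growth = growth,
    translations = translations, clinical = clin,
    grid = grid, grid_center = grid_center, box = box, solver = solver,
    prep = list(window = window, smooth_step = smooth_step,
                smooth_steps = smooth_steps, midsagittal = midsagittal,
                location_invariant = location_invariant),
    n = length(cohort)),
    class = "tbm")
}

# Shared preprocessing for one cohort record.
preprocess_record <- function(r, window = c(0, 150), smooth_step = 0.125,
                              smooth_steps = 5, midsagittal = NULL,
                              center_at = NULL) {
  img <- window_hu(r$image, window[1], window[2])
  msk <- r$mask
  mirrored <- FALSE
  if (!is.null(midsagittal)) {
    mm <- mask_and_mirror(img, msk, midsagittal)
    img <- mm$image; msk <- mm$mask; mirrored <- mm$mirrored
  } else {
    img$data <- img$data * msk$data
  }
  translation <- c(0, 0, 0)
  if (!is.null(center_at)) {
    li <- make_location_invariant(img, msk, center_at)
    img <- li$image; msk <- li$mask; translation <- li$translation
  }
  img <- smooth_curvature(img, smooth_step, smooth_steps)
  img <- normalize_mass(img)
  list(image = img, mask = msk, translation = translation,
       mirrored = mirrored)
}

#' @export
print.tbm <- function(x, ...) {
  cat(sprintf("<tbm> %d subjects, %s grid, %d PCs (%.0f%% var), covariates: %s\n",
              x$n, paste(x$grid$shape, collapse = "x"),
              x$pca$n_retained, 100 * x$pca$var_frac, x$covariates))
  if (!is.null(x$plda))
    cat(sprintf("  expansion pLDA: lambda %g, training AUROC %.3f\n",
                x$plda$lambda,
                auroc_rank(predict(x$plda, x$feats), x$labels)))
  if (!is.null(x$cca))
    cat(sprintf("  growth CCA: training correlation %.3f\n", x$cca$train_cor))
  invisible(x)
}

#' @export
summary.tbm <- function(object, ...) {
  out <- list(
    n = object$n,
    n_retained = object$pca$n_retained,
    explained = sum(object$pca$explained[seq_len(object$pca$n_retained)]),
    prevalence = mean(object$labels),
    covariates = object$covariates,
    template_iterations = object$template$n_iterations,
    template_costs = object$template$mean_cost)
  if (!is.null(object$plda)) {
    sc <- predict(object$plda, object$feats)
    out$train_metrics <- classification_metrics(sc, object$labels,
                                                object$plda$threshold)
    out$lambda <- object$plda$lambda
  }
  if (!is.null(object$cca)) out$train_cor <- object$cca$train_cor
  class(out) <- "summary.tbm"
  out
}

#' @export
print.summary.tbm <- function(x, ...) {
  cat(sprintf("Transport-based morphometry fit (n = %d)\n", x$n))
  cat(sprintf("  PCA: %d components, %.1f%% variance\n", x$n_retained,
              100 * x$explained))
  cat(sprintf("  template: %d iterations, mean cost %s\n",
              x$template_iterations,
              paste(sprintf("%.4f", x$template_costs), collapse = " -> ")))
  cat(sprintf("  expansion prevalence: %.2f, covariates: %s\n", x$prevalence,
              x$covariates))
  if (!is.null(x$train_metrics)) {
    m <- x$train_metrics
    cat(sprintf("  training AUROC %.3f, acc %.3f, sens %.3f, spec %.3f\n",
                m$auroc, m$accuracy, m$sensitivity, m$specificity))
  }
  if (!is.null(x$train_cor))
    cat(sprintf("  training growth correlation %.3f\n", x$train_cor))
  invisible(x)
}

#' Model directions
#'
#' @param object a fitted [tbm()] model.
#' @param which `"plda"` or `"cca"`.
#' @param space `"reduced"` (model feature space) or `"embedding"`
#'   (displacement-field space, image block only).
#' @param ... unused.
#' @return Numeric vector.
#' @export
coef.tbm <- function(object, which = c("plda", "cca"),
                     space = c("reduced", "embedding"), ...) {
  which <- match.arg(which)
  space <- match.arg(space)
  fit <- object[[which]]
  if (is.null(fit))
    tb_stop("tb_invalid_parameter", sprintf("model has no %s fit", which))
  w <- fit$direction
  if (space == "reduced") return(w)
  k <- object$pca$n_retained
  wi <- w[seq_len(k)]
  if (!is.null(object$aug_params)) wi <- wi / object$aug_params$sd[seq_len(k)]
  drop(object$pca$rotation[, seq_len(k), drop = FALSE] %*% wi)
}

#' Predict expansion or growth for new subjects
#'
#' New subjects are preprocessed with the training protocol, embedded
#' against the fitted template, projected through the training PCA and
#' standardization, and scored by the trained direction(s).
#'
#' @param object a fitted [tbm()] model.
#' @param newdata a `tbm_cohort` on the same grid.
#' @param type `"score"` (discriminant projection), `"class"` (thresholded
#'   expansion call) or `"growth"` (CCA projection).
#' @param ... unused.
#' @return Numeric or logical vector, one element per subject.
#' @export
predict.tbm <- function(object, newdata,
                        type = c("score", "class", "growth"), ...) {
  type <- match.arg(type)
  feats <- tbm_features(object, newdata)
  if (type == "growth") {
    if (is.null(object$cca)) tb_stop("tb_invalid_parameter", "no CCA fit")
    return(predict(object$cca, feats))
  }
  if (is.null(object$plda)) tb_stop("tb_invalid_parameter", "no pLDA fit")
  predict(object$plda, feats,
          type = if (type == "class") "class" else "score")
}

# Embed new records and build model-space features with training transforms.
tbm_features <- function(object, cohort) {
  prep <- lapply(cohort, function(r) {
    preprocess_record(r, window = object$prep$window,
                      smooth_step = object$prep$smooth_step,
                      smooth_steps = object$prep$smooth_steps,
                      midsagittal = object$prep$midsagittal,
                      center_at = if (object$prep$location_invariant)
                        object$grid_center)
  })
  images <- lapply(prep, `[[`, "image")
  box <- support_box(c(list(object$template$image), images))
  maps <- lapply(images, solve_mp_map, I0 = object$template$image,
                 cfg = object$solver, crop = box)
  X <- do.call(rbind, lapply(maps, function(m) as.numeric(lot_embed(m))))
  scores <- predict(object$pca, X)
  if (is.null(object$aug_params)) return(scores)
  translations <- do.call(rbind, lapply(prep, `[[`, "translation"))
  colnames(translations) <- c("tx", "ty", "tz")
  clin <- do.call(rbind, lapply(cohort, `[[`, "covariates"))
  covmat <- switch(object$covariates,
    "location" = translations,
    "location+clinical" = cbind(translations, clin))
  augment_features(scores, covmat[, 0, drop = FALSE], covmat,
                   params = object$aug_params)$a
}

#' Traversal montage of a fitted model direction
#'
#' Renders the generative traversal of the discriminant (or correlation)
#' direction as a row of axial overlays on the template.
#'
#' @param x a fitted [tbm()] model.
#' @param which `"plda"` or `"cca"`.
#' @param sigmas traversal positions in SDs of the projected training data.
#' @param slice_index axial slice (1-based; default: template center slice).
#' @param ... unused.
#' @return Invisibly, the list of traversal images.
#' @export
plot.tbm <- function(x, which = c("plda", "cca"), sigmas = c(-2, 0, 2),
                     slice_index = NULL, ...) {
  which <- match.arg(which)
  trav <- traverse_direction(x, which = which, sigmas = sigmas)
  if (is.null(slice_index))
    slice_index <- round(com_voxel(x$template$image$data)[3])
  op <- par(mfrow = c(1, length(sigmas)), mar = c(0.5, 0.5, 2, 0.5))
  on.exit(par(op))
  for (i in seq_along(sigmas)) {
    ov <- overlay_render(x$template$image, trav$images[[i]],
                         plane = "axial", slice_index = slice_index)
    plot.new()
    plot.window(c(0, 1), c(0, 1), asp = ncol(ov$rgb) / nrow(ov$rgb))
    rasterImage(ov$rgb, 0, 0, 1, 1)
    title(sprintf("sigma = %+.1f", sigmas[i]))
  }
  invisible(trav)
}
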