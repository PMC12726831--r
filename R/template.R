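#' Voxelwise Euclidean mean of normalized images
#'
#' @param images list of [vol_img()] (`normalized-mass`) on a shared grid.
#' @return A [vol_img()] with unit mass.
#' @export
euclidean_mean <- function(images) {
  if (length(images) < 1) tb_stop("tb_invalid_parameter", "need >= 1 image")
  for (im in images[-1]) stopifnot_same_grid(images[[1]], im)
  acc <- images[[1]]$data
  for (im in images[-1]) acc <- acc + im$data
  out <- images[[1]]
  out$data <- acc / length(images)
  normalize_mass(out)
}

#' Intrinsic mean template of a set of lesion images
#'
#' Estimates the reference image for the LOT embedding: starting from the
#' Euclidean mean `mu`, iteratively (a) solves the mass-preserving maps `f_k`
#' that transform each image into the current template (subject as source),
#' (b) averages the maps voxelwise, and (c) re-synthesizes the template by
#' pulling the current template through the averaged map,
#' `I0_new(x) = det(Dfbar(x)) I0(fbar(x))` (at the first iteration `I0 = mu`,
#' the Euclidean mean). With a single image this reproduces that image in one
#' step; with translated copies it converges to the mid-position shape.
#' Iterations stop when the mean transport cost changes by less than `tol`
#' (relative) or after `max_outer` rounds. If the averaged map folds
#' (negative determinant on the support), the update is damped toward the
#' identity until admissible.
#'
#' @param images list of [vol_img()] (`normalized-mass`) on a shared grid.
#' @param cfg a [solver_config()] used for every member map.
#' @param max_outer maximum outer iterations.
#' @param tol relative mean-cost change tolerance.
#' @param crop optional common support box passed to [solve_mp_map()].
#' @param verbose print per-iteration mean transport cost.
#' @return An object of class `template_model` with fields `image` (the
#'   template), `mean_cost` (per-iteration mean squared transport cost, mm^2),
#'   `n_iterations`, `converged`.
#' @export
intrinsic_mean <- function(images, cfg = solver_config(), max_outer = 10,
                           tol = 1e-3, crop = NULL, verbose = FALSE) {
  if (length(images) < 2) tb_stop("tb_invalid_parameter", "need >= 2 images")
  mu <- euclidean_mean(images)
  I0 <- mu
  costs <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_outer)) {
    maps <- lapply(seq_along(images), function(k) {
      m <- tryCatch(solve_mp_map(images[[k]], I0, cfg, crop = crop),
                    error = function(e) {
                      tb_stop("tb_solver_failure",
                              sprintf("map for subject %d failed: %s", k,
                                      conditionMessage(e)))
                    })
      m
    })
    mc <- mean(vapply(maps, function(m) m$transport_cost, 0))
    if (verbose)
      message(sprintf("template iteration %d: mean transport cost %.5f", it, mc))
    if (length(costs) && mc > costs[length(costs)]) {
      # monotone safeguard: reject an update that increased the mean
      # transport cost and keep the previous template
      I0 <- prev_I0
      converged <- TRUE
      break
    }
    improved <- length(costs) == 0 ||
      (costs[length(costs)] - mc) > tol * max(costs[length(costs)], 1e-12)
    costs <- c(costs, mc)
    if (!improved) {
      converged <- TRUE
      break
    }
    prev_I0 <- I0
    # voxelwise average of the maps (displacement mean)
    ub <- maps[[1]]$u
    for (m in maps[-1]) ub <- ub + m$u
    ub <- ub / length(maps)
    # damped update if the averaged map folds on the support
    eta <- 1
    repeat {
      ue <- ub * eta
      M <- jac_entries(list(array(ue[, , , 1], I0$shape),
                            array(ue[, , , 2], I0$shape),
                            array(ue[, , , 3], I0$shape)))
      det <- jac_det(M)
      supp <- I0$data > max(I0$data) * 1e-6
      if (all(det[supp] > 0) || eta < 1 / 64) break
      eta <- eta / 2
    }
    # I0_new(x) = det(Dfbar(x)) I0(fbar(x)) with fbar = id + eta*ubar
    cc <- coord_arrays(I0$shape)
    newd <- pmax(det, 0) *
      array(interp3(I0$data, cc$x + array(ue[, , , 1], I0$shape),
                    cc$y + array(ue[, , , 2], I0$shape),
                    cc$z + array(ue[, , , 3], I0$shape)), I0$shape)
    if (sum(newd) <= 0)
      tb_stop("tb_solver_failure", "template update produced an empty image")
    I0$data <- newd / sum(newd)
  }
  structure(list(image = I0, euclidean_mean = mu, mean_cost = costs,
                 n_iterations = length(costs), converged = converged),
            class = "template_model")
}

#' @export
print.template_model <- function(x, ...) {
  cat(sprintf("<template_model> %s grid, %d iterations (%s), mean cost %s\n",
              paste(x$image$shape, collapse = "x"), x$n_iterations,
              if (x$converged) "converged" else "max iterations",
              paste(sprintf("%.4f", x$mean_cost), collapse = " -> ")))
  invisible(x)
}

#' Center of mass of a mask or image in world coordinates (mm)
#'
#' @param x a [vol_img()] or [seg_mask()].
#' @return Numeric length 3 (mm).
#' @export
center_of_mass <- function(x) {
  cv <- com_voxel(x$data)
  x$origin + (cv - 1) * x$spacing
}
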