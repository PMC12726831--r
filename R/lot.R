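#' Solver configuration for mass-preserving transport maps
#'
#' The map is found by penalized variational descent over a displacement
#' field: the objective is the mass-weighted transport cost plus a penalty on
#' the mass-preservation residual `det(Df) * I1(f) - I0` (relative L2) and a
#' curl penalty that keeps the field close to a gradient field. Descent runs
#' over a multiresolution pyramid and is initialized at the coarsest level by
#' the separable 1D marginal CDF-rearrangement map. The solver is
#' deterministic: identical inputs and config give identical maps.
#'
#' @param n_levels multiresolution levels (>= 1).
#' @param max_iters maximum descent iterations per level.
#' @param tol relative objective-change stopping tolerance.
#' @param mp_penalty weight of the (relative) mass-preservation residual.
#' @param curl_penalty weight of the mean squared curl of the field.
#' @param smooth_penalty weight of the elastic (mean squared displacement
#'   gradient) regularizer.
#' @param epsilon_floor total mass floor spread over all voxels before
#'   normalization, making measures strictly positive.
#' @param mp_tol residual level below which a map is declared converged.
#' @param fold_penalty weight of the hinge barrier on the Jacobian
#'   determinant that keeps the map orientation-preserving.
#' @param det_min determinant level below which the fold barrier engages.
#' @param mass_penalty weight of the squared total-mass deviation of the
#'   pushed-forward reference, enforcing global mass conservation.
#' @param attach_weight uniform cost attachment (fraction of total mass,
#'   spread over the grid) pulling the field to zero in massless regions.
#' @param polish run a final descent pass with the MP penalty hardened 100x.
#' @return A list of class `solver_config`.
#' @export
solver_config <- function(n_levels = 3, max_iters = 60, tol = 1e-5,
                          mp_penalty = 1000, curl_penalty = 1,
                          smooth_penalty = 2, epsilon_floor = 1e-8,
                          mp_tol = 0.1, fold_penalty = 1e5, det_min = 0.1,
                          mass_penalty = 1e5, attach_weight = 1e-3,
                          polish = TRUE) {
  stopifnot(n_levels >= 1, max_iters >= 1, tol > 0, tol < 1,
            mp_penalty > 0, curl_penalty >= 0, smooth_penalty >= 0,
            epsilon_floor > 0, fold_penalty >= 0, attach_weight >= 0)
  structure(list(n_levels = as.integer(n_levels),
                 max_iters = as.integer(max_iters), tol = tol,
                 mp_penalty = mp_penalty, curl_penalty = curl_penalty,
                 smooth_penalty = smooth_penalty,
                 epsilon_floor = epsilon_floor, mp_tol = mp_tol,
                 fold_penalty = fold_penalty, det_min = det_min,
                 mass_penalty = mass_penalty,
                 attach_weight = attach_weight, polish = isTRUE(polish)),
            class = "solver_config")
}

# Deterministic short identifier for a reference image.
ref_id <- function(v) {
  x <- as.vector(v$data)
  h <- sum(x * (seq_along(x) %% 997L)) + 31 * sum(x * x)
  sprintf("ref-%s-%s", paste(dim(v$data), collapse = "x"),
          format(h, digits = 12))
}

# Monotone 1D rearrangement: continuous (1-based) target coordinate for each
# source voxel center, by matching midpoint CDFs of densities p -> q.
rearrange_1d <- function(p, q) {
  n <- length(p)
  p <- p / sum(p); q <- q / sum(q)
  mid0 <- cumsum(p) - p / 2
  mid1 <- cumsum(q) - q / 2
  approx(x = mid1, y = seq_len(n), xout = mid0, rule = 2, ties = "ordered")$y
}

# Separable product-of-marginals rearrangement map (exact optimal transport
# for separable densities); returns a displacement list (voxel units).
sep_init <- function(I0a, I1a) {
  d <- dim(I0a)
  u <- vector("list", 3)
  for (ax in 1:3) {
    m0 <- apply(I0a, ax, sum)
    m1 <- apply(I1a, ax, sum)
    tgt <- rearrange_1d(m0, m1)
    # taper the map toward identity where the source marginal carries no
    # mass: the rearrangement is meaningless in floor-level tails
    wgt <- m0 / (m0 + 1e-6 * max(m0))
    disp <- (tgt - seq_len(d[ax])) * wgt
    u[[ax]] <- switch(ax,
      array(rep(disp, times = d[2] * d[3]), dim = d),
      array(rep(rep(disp, each = d[1]), times = d[3]), dim = d),
      array(rep(disp, each = d[1] * d[2]), dim = d))
  }
  u
}

# Displacement Jacobian entries M = I + Du (central differences).
jac_entries <- function(u) {
  list(
    m11 = 1 + central_diff(u[[1]], 1), m12 = central_diff(u[[1]], 2),
    m13 = central_diff(u[[1]], 3),
    m21 = central_diff(u[[2]], 1), m22 = 1 + central_diff(u[[2]], 2),
    m23 = central_diff(u[[2]], 3),
    m31 = central_diff(u[[3]], 1), m32 = central_diff(u[[3]], 2),
    m33 = 1 + central_diff(u[[3]], 3))
}

jac_det <- function(M) {
  M$m11 * (M$m22 * M$m33 - M$m23 * M$m32) -
    M$m12 * (M$m21 * M$m33 - M$m23 * M$m31) +
    M$m13 * (M$m21 * M$m32 - M$m22 * M$m31)
}

# Objective and (optionally) gradient of the penalized MP functional.
# Thin wrapper over the C++ kernel; the pure-R reference implementation
# below is retained as an independent cross-check for tests.
mp_objective <- function(u, env, want_grad = FALSE) {
  cfg <- env$cfg
  p <- if (is.list(u)) c(u[[1]], u[[2]], u[[3]]) else u
  res <- .cpp_mp_objective(p, env$I0a, env$I1a,
                           dim(env$I0a), env$attach, env$I0_ss,
                           cfg$mp_penalty, cfg$curl_penalty,
                           cfg$smooth_penalty, cfg$fold_penalty,
                           cfg$det_min, cfg$mass_penalty, want_grad)
  out <- list(J = res$J, cost = res$cost, mp = res$mp, curl = res$curl,
              elas = res$elas, fold = res$fold,
              mp_residual = res$mp_residual, min_det = res$min_det)
  if (want_grad) {
    d <- dim(env$I0a)
    n <- prod(d)
    out$grad <- list(array(res$grad[seq_len(n)], d),
                     array(res$grad[n + seq_len(n)], d),
                     array(res$grad[2 * n + seq_len(n)], d))
  }
  out
}

mp_objective_ref <- function(u, env, want_grad = FALSE) {
  I0a <- env$I0a
  d <- dim(I0a)
  cc <- env$cc
  fx <- cc$x + u[[1]]; fy <- cc$y + u[[2]]; fz <- cc$z + u[[3]]
  M <- jac_entries(u)
  det <- jac_det(M)
  W <- array(interp3(env$I1a, fx, fy, fz), dim = d)
  r <- det * W - I0a
  # cost weight: reference mass plus a tiny uniform attachment that pulls
  # the field to zero wherever there is no mass to move
  Wc <- I0a + env$attach
  cost <- sum(Wc * (u[[1]]^2 + u[[2]]^2 + u[[3]]^2))
  mp <- sum(r * r) / env$I0_ss
  # curl from the Jacobian entries already computed (m_ij = D_j u_i)
  w1 <- M$m32 - M$m23
  w2 <- M$m13 - M$m31
  w3 <- M$m21 - M$m12
  curl <- sum(w1^2 + w2^2 + w3^2) / prod(d)
  # elastic smoothness: mean squared displacement gradient, suppressing
  # grid-scale oscillation the data terms cannot see
  elas <- (sum((M$m11 - 1)^2 + M$m12^2 + M$m13^2) +
             sum(M$m21^2 + (M$m22 - 1)^2 + M$m23^2) +
             sum(M$m31^2 + M$m32^2 + (M$m33 - 1)^2)) / prod(d)
  # mass-weighted hinge barrier keeping the map orientation-preserving
  # (det >= det_min) wherever there is mass to invert
  hinge <- pmax(env$cfg$det_min - det, 0)
  fold <- sum(Wc * hinge^2)
  rsum <- sum(r)
  J <- cost + env$cfg$mp_penalty * mp + env$cfg$curl_penalty * curl +
    env$cfg$smooth_penalty * elas + env$cfg$fold_penalty * fold +
    env$cfg$mass_penalty * rsum^2
  out <- list(J = J, cost = cost, mp = mp, curl = curl, fold = fold,
              elas = elas, mp_residual = sqrt(mp), det = det,
              min_det = min(det), mass_dev = rsum)
  if (!want_grad) return(out)
  # cofactors of M
  C11 <- M$m22 * M$m33 - M$m23 * M$m32
  C12 <- -(M$m21 * M$m33 - M$m23 * M$m31)
  C13 <- M$m21 * M$m32 - M$m22 * M$m31
  C21 <- -(M$m12 * M$m33 - M$m13 * M$m32)
  C22 <- M$m11 * M$m33 - M$m13 * M$m31
  C23 <- -(M$m11 * M$m32 - M$m12 * M$m31)
  C31 <- M$m12 * M$m23 - M$m13 * M$m22
  C32 <- -(M$m11 * M$m23 - M$m13 * M$m21)
  C33 <- M$m11 * M$m22 - M$m12 * M$m21
  gW <- interp3_partials(env$I1a, fx, fy, fz)
  g1 <- array(gW$gx, dim = d)
  g2 <- array(gW$gy, dim = d)
  g3 <- array(gW$gz, dim = d)
  rw <- r * W
  N <- prod(d)
  k_mp <- 2 * env$cfg$mp_penalty / env$I0_ss
  k_c <- 2 * env$cfg$curl_penalty / N
  k_e <- 2 * env$cfg$smooth_penalty / N
  k_f <- 2 * env$cfg$fold_penalty
  # all divergence-form terms (MP, fold, elastic, curl) merged into a single
  # central-difference pass over the 9 integrands S_ij, grad_i += sum_j D_j S_ij
  cm <- 2 * env$cfg$mass_penalty * rsum
  cof_mult <- -k_mp * rw + k_f * Wc * hinge - cm * W
  S11 <- cof_mult * C11 - k_e * (M$m11 - 1)
  S12 <- cof_mult * C12 - k_e * M$m12 + k_c * w3
  S13 <- cof_mult * C13 - k_e * M$m13 - k_c * w2
  S21 <- cof_mult * C21 - k_e * M$m21 - k_c * w3
  S22 <- cof_mult * C22 - k_e * (M$m22 - 1)
  S23 <- cof_mult * C23 - k_e * M$m23 + k_c * w1
  S31 <- cof_mult * C31 - k_e * M$m31 + k_c * w2
  S32 <- cof_mult * C32 - k_e * M$m32 - k_c * w1
  S33 <- cof_mult * C33 - k_e * (M$m33 - 1)
  rdet <- k_mp * r * det + cm * det
  gu1 <- 2 * Wc * u[[1]] + rdet * g1 +
    central_diff(S11, 1) + central_diff(S12, 2) + central_diff(S13, 3)
  gu2 <- 2 * Wc * u[[2]] + rdet * g2 +
    central_diff(S21, 1) + central_diff(S22, 2) + central_diff(S23, 3)
  gu3 <- 2 * Wc * u[[3]] + rdet * g3 +
    central_diff(S31, 1) + central_diff(S32, 2) + central_diff(S33, 3)
  out$grad <- list(gu1, gu2, gu3)
  out
}

# Quasi-Newton (L-BFGS) minimization of the penalized functional at one
# resolution level. The objective is guarded so the line search never
# accepts a worse point than the best seen.
descend_level <- function(u, I0a, I1a, cfg) {
  d <- dim(I0a)
  env <- list(I0a = I0a, I1a = I1a, cc = coord_arrays(d),
              I0_ss = sum(I0a^2), cfg = cfg,
              attach = cfg$attach_weight / prod(d))
  n <- prod(d)
  par2u <- function(p) list(array(p[seq_len(n)], d),
                            array(p[n + seq_len(n)], d),
                            array(p[2 * n + seq_len(n)], d))
  kernel <- function(p, want_grad) {
    .cpp_mp_objective(p, env$I0a, env$I1a, d, env$attach, env$I0_ss,
                      cfg$mp_penalty, cfg$curl_penalty, cfg$smooth_penalty,
                      cfg$fold_penalty, cfg$det_min, cfg$mass_penalty,
                      want_grad)
  }
  n_eval <- 0L
  fn <- function(p) {
    n_eval <<- n_eval + 1L
    kernel(p, FALSE)$J
  }
  gr <- function(p) kernel(p, TRUE)$grad
  p0 <- c(u[[1]], u[[2]], u[[3]])
  J0 <- kernel(p0, FALSE)$J
  opt <- stats::optim(p0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = cfg$max_iters,
                                     factr = cfg$tol / 1e-15, pgtol = 0))
  if (opt$value <= J0) {
    u <- par2u(opt$par)
  }
  ev <- mp_objective(u, env, want_grad = FALSE)
  list(u = u, eval = ev, iterations = n_eval, trace = c(J0, ev$J))
}

floor_normalize <- function(a, epsilon_floor) {
  a <- a / sum(a)
  a <- a + epsilon_floor / length(a)
  a / sum(a)
}

#' Support bounding box of one or more images
#'
#' Axis-aligned voxel index ranges covering every voxel whose intensity
#' exceeds `thr_rel` times the image maximum, padded by `margin` voxels.
#' Used to restrict the transport solve to the region that carries mass;
#' pass the box to [solve_mp_map()] (e.g. a cohort-wide union box) so all
#' embeddings share the same convention outside the lesions.
#'
#' @param images list of [vol_img()] on a common grid.
#' @param thr_rel relative intensity threshold defining support.
#' @param margin padding in voxels.
#' @return List of three integer ranges `c(lo, hi)` (1-based).
#' @export
support_box <- function(images, thr_rel = 1e-7, margin = 5L) {
  shape <- images[[1]]$shape
  lo <- shape; hi <- c(1L, 1L, 1L)
  for (im in images) {
    s <- im$data > max(im$data) * thr_rel
    for (ax in 1:3) {
      pr <- apply(s, ax, any)
      w <- which(pr)
      lo[ax] <- min(lo[ax], w[1])
      hi[ax] <- max(hi[ax], w[length(w)])
    }
  }
  lapply(1:3, function(ax) c(max(1L, lo[ax] - margin),
                             min(shape[ax], hi[ax] + margin)))
}

#' Solve the mass-preserving optimal transport map between two images
#'
#' Finds a deformation `f(x) = x + u(x)` from the reference `I0` to the
#' subject `I1` that approximately satisfies the mass-preservation constraint
#' `det(Df) * I1(f(x)) = I0(x)` while minimizing the quadratic transport cost
#' `sum I0(x) |f(x) - x|^2`. The achieved cost is the squared Wasserstein
#' distance estimate between the two measures.
#'
#' @param I0 reference [vol_img()], `normalized-mass` units.
#' @param I1 target [vol_img()] on the same grid, `normalized-mass` units.
#' @param cfg a [solver_config()].
#' @param crop `NULL` to restrict the solve automatically to the joint
#'   [support_box()] of the two images, `FALSE` to solve on the full grid, or
#'   an explicit box (list of three `c(lo, hi)` ranges). Outside the box the
#'   displacement is zero.
#' @return An object of class `transport_map` with the displacement field `u`
#'   (4D array, last dimension = component, voxel units), `transport_cost`
#'   (mm^2), `mp_residual`, `converged`, `iterations`.
#' @export
solve_mp_map <- function(I0, I1, cfg = solver_config(), crop = NULL) {
  stopifnot_same_grid(I0, I1)
  if (I0$units != "normalized-mass" || I1$units != "normalized-mass")
    tb_stop("tb_bad_units", "solve_mp_map expects normalized-mass images")
  if (abs(sum(I0$data) - 1) > 1e-6 || abs(sum(I1$data) - 1) > 1e-6)
    tb_stop("tb_bad_units", "input masses must sum to 1")
  full_shape <- I0$shape
  full_ref <- ref_id(I0)
  if (isTRUE(crop)) crop <- NULL
  box <- NULL
  if (!isFALSE(crop)) {
    box <- if (is.null(crop)) support_box(list(I0, I1)) else crop
    if (prod(vapply(box, diff, 0) + 1) < 0.9 * prod(full_shape)) {
      sub <- function(v) {
        v$data <- v$data[box[[1]][1]:box[[1]][2], box[[2]][1]:box[[2]][2],
                         box[[3]][1]:box[[3]][2], drop = FALSE]
        v$shape <- dim(v$data)
        normalize_mass(v)
      }
      I0 <- sub(I0); I1 <- sub(I1)
    } else {
      box <- NULL
    }
  }
  shape <- I0$shape
  I0a <- floor_normalize(I0$data, cfg$epsilon_floor)
  I1a <- floor_normalize(I1$data, cfg$epsilon_floor)
  # multiresolution pyramid (coarsest first)
  n_lev <- cfg$n_levels
  while (n_lev > 1 && min(ceiling(shape / 2^(n_lev - 1))) < 8) n_lev <- n_lev - 1
  pyr0 <- list(I0a); pyr1 <- list(I1a)
  if (n_lev > 1) {
    for (l in 2:n_lev) {
      pyr0[[l]] <- floor_normalize(downsample2(pyr0[[l - 1]]), cfg$epsilon_floor)
      pyr1[[l]] <- floor_normalize(downsample2(pyr1[[l - 1]]), cfg$epsilon_floor)
    }
  }
  u <- sep_init(pyr0[[n_lev]], pyr1[[n_lev]])
  iters <- 0L
  if (n_lev > 1) {
    for (l in rev(seq(2, n_lev))) {
      res <- descend_level(u, pyr0[[l]], pyr1[[l]], cfg)
      u <- res$u
      iters <- iters + res$iterations
      ns <- dim(pyr0[[l - 1]])
      os <- dim(pyr0[[l]])
      sc <- (ns - 1) / pmax(os - 1, 1)
      u <- lapply(1:3, function(i) resample3(u[[i]], ns) * sc[i])
    }
    # the coarse detour helps multimodal problems but can leave a worse
    # basin than the direct fine-grid rearrangement start (which is exact
    # for separable inputs); start the fine descent from whichever is better
    env_f <- list(I0a = pyr0[[1]], I1a = pyr1[[1]],
                  I0_ss = sum(pyr0[[1]]^2), cfg = cfg,
                  attach = cfg$attach_weight / length(pyr0[[1]]))
    u_direct <- sep_init(pyr0[[1]], pyr1[[1]])
    if (mp_objective(u_direct, env_f)$J < mp_objective(u, env_f)$J)
      u <- u_direct
  }
  res <- descend_level(u, pyr0[[1]], pyr1[[1]], cfg)
  u <- res$u
  iters <- iters + res$iterations
  # polish phase: re-descend at the finest level with a hardened
  # mass-preservation penalty so the constraint residual, not the cost
  # trade-off, sets the final accuracy
  if (cfg$polish) {
    cfg_p <- cfg
    cfg_p$mp_penalty <- cfg$mp_penalty * 100
    cfg_p$max_iters <- max(10L, cfg$max_iters %/% 2L)
    res <- descend_level(u, pyr0[[1]], pyr1[[1]], cfg_p)
    u <- res$u
    iters <- iters + res$iterations
  }
  ev <- res$eval
  sp <- I0$spacing
  cost_mm2 <- sum(pyr0[[1]] * ((u[[1]] * sp[1])^2 + (u[[2]] * sp[2])^2 +
                                 (u[[3]] * sp[3])^2))
  ua <- array(0, dim = c(full_shape, 3))
  if (is.null(box)) {
    ua[, , , 1] <- u[[1]]; ua[, , , 2] <- u[[2]]; ua[, , , 3] <- u[[3]]
  } else {
    for (i in 1:3)
      ua[box[[1]][1]:box[[1]][2], box[[2]][1]:box[[2]][2],
         box[[3]][1]:box[[3]][2], i] <- u[[i]]
  }
  structure(list(u = ua, shape = full_shape, spacing = sp, origin = I0$origin,
                 reference_id = full_ref,
                 mp_residual = ev$mp_residual,
                 transport_cost = cost_mm2,
                 min_det = ev$min_det,
                 converged = ev$mp_residual <= cfg$mp_tol,
                 iterations = iters, objective = ev$J),
            class = "transport_map")
}

#' @export
print.transport_map <- function(x, ...) {
  cat(sprintf(paste0("<transport_map> %s grid, W2 ~ %.3f mm, MP residual %.4f,",
                     " %s (%d iterations)\n"),
              paste(x$shape, collapse = "x"), sqrt(max(x$transport_cost, 0)),
              x$mp_residual, if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

#' Wasserstein distance achieved by a transport map
#'
#' @param map a `transport_map` from [solve_mp_map()].
#' @return Distance in mm (`sqrt` of the achieved transport cost). A warning
#'   is raised for unconverged maps.
#' @export
wasserstein_distance <- function(map) {
  if (!map$converged)
    warning("transport map did not converge; distance may be inaccurate")
  sqrt(max(map$transport_cost, 0))
}

#' Linear optimal transport embedding of a transport map
#'
#' Flattens the displacement field into a fixed-order vector (x-fastest
#' within each component; components concatenated). The stored field uses the
#' generative sign convention `v(x) = x - f(x)`, so that the same vector can
#' be passed to [invert_embedding()] to resynthesize the image the map points
#' to, and linear combinations of embeddings remain invertible displacement
#' fields.
#'
#' @param map a `transport_map`.
#' @return A numeric vector of class `lot_embedding` with grid metadata
#'   attributes; length `3 * prod(shape)`.
#' @export
lot_embed <- function(map) {
  v <- -as.vector(map$u)
  structure(v, class = "lot_embedding", reference_id = map$reference_id,
            shape = map$shape, spacing = map$spacing, origin = map$origin)
}

embedding_field <- function(e) {
  array(as.numeric(e), dim = c(attr(e, "shape"), 3))
}

#' LOT distance between two embeddings
#'
#' L2 norm of the difference of the two displacement fields over the
#' reference domain (voxel quadrature; displacements scaled to mm by the
#' grid spacing).
#'
#' @param e1,e2 `lot_embedding` objects sharing reference and grid.
#' @return Distance (mm . mm^(3/2), from the volume quadrature).
#' @export
lot_distance <- function(e1, e2) {
  if (!identical(attr(e1, "reference_id"), attr(e2, "reference_id")) ||
      !identical(attr(e1, "shape"), attr(e2, "shape")))
    tb_stop("tb_reference_mismatch",
            "embeddings have different references or grids")
  sp <- attr(e1, "spacing")
  n <- prod(attr(e1, "shape"))
  d <- as.numeric(e1) - as.numeric(e2)
  ss <- sum((d[seq_len(n)] * sp[1])^2) +
    sum((d[n + seq_len(n)] * sp[2])^2) +
    sum((d[2 * n + seq_len(n)] * sp[3])^2)
  sqrt(ss * prod(sp))
}

#' Synthesize an image from a displacement field (generative inversion)
#'
#' Given a displacement field `v` on the reference grid, forms the map
#' `f_v(x) = x - v(x)`, numerically inverts it, and pulls the reference
#' through it: `I_v(y) = det(Dg(y)) I0(g(y))` with `g = f_v^{-1}`. This is
#' the generative direction of the LOT representation: the field of a solved
#' map reproduces its subject image, and any point of transport space (e.g. a
#' model traversal) can be rendered the same way.
#'
#' @param v a `lot_embedding`, a 4D displacement array `(nx,ny,nz,3)`, or a
#'   `transport_map`.
#' @param I0 the reference [vol_img()] (`normalized-mass`).
#' @param method `"pullback"` (default) computes `det(Dg) I0(g)` through the
#'   Newton-inverted map and requires `f_v` to be orientation-preserving on
#'   the support of `I0`; `"pushforward"` deposits the reference mass at the
#'   mapped positions with conservative trilinear weights, which is defined
#'   (if diffusive) even for folded fields — useful for extreme traversals.
#' @return A [vol_img()] in `normalized-mass` units.
#' @export
invert_embedding <- function(v, I0, method = c("pullback", "pushforward")) {
  method <- match.arg(method)
  if (inherits(v, "transport_map")) {
    va <- -v$u
  } else if (inherits(v, "lot_embedding")) {
    va <- embedding_field(v)
  } else {
    va <- v
  }
  shape <- I0$shape
  stopifnot(all(dim(va) == c(shape, 3)))
  v1 <- array(va[, , , 1], dim = shape)
  v2 <- array(va[, , , 2], dim = shape)
  v3 <- array(va[, , , 3], dim = shape)
  if (method == "pushforward") {
    cc <- coord_arrays(shape)
    img <- splat3(I0$data, cc$x - v1, cc$y - v2, cc$z - v3)
    if (sum(img) <= 0)
      tb_stop("tb_inversion_failure", "synthesized image has no mass")
    return(vol_img(img / sum(img), spacing = I0$spacing, origin = I0$origin,
                   units = "normalized-mass"))
  }
  # admissibility: det(D f_v) > 0 on the (numerical) support of I0 — the
  # region holding non-negligible mass; folds in the 1e-3-of-peak fringe
  # cannot move appreciable mass and are tolerated
  M <- jac_entries(list(-v1, -v2, -v3))
  detf <- jac_det(M)
  supp <- I0$data > max(I0$data) * 1e-3
  if (any(detf[supp] <= 0)) {
    worst <- which.min(detf * supp + !supp * Inf)
    idx <- arrayInd(worst, shape)
    tb_stop("tb_inversion_failure",
            sprintf("field is not invertible on the support (det=%.4f at voxel %d,%d,%d)",
                    min(detf[supp]), idx[1], idx[2], idx[3]))
  }
  cc <- coord_arrays(shape)
  # invert y = f_v(g(y)) = g - v(g) by vectorized Newton iteration, then
  # pull the reference back through the inverse: I_v = det(Dg) I0(g). Using
  # the same trilinear interpolation and central-difference Jacobian as the
  # solver makes the round trip consistent to the solver's MP residual.
  dv <- list(lapply(1:3, function(ax) central_diff(v1, ax)),
             lapply(1:3, function(ax) central_diff(v2, ax)),
             lapply(1:3, function(ax) central_diff(v3, ax)))
  gx <- cc$x + v1; gy <- cc$y + v2; gz <- cc$z + v3
  for (it in 1:20) {
    r1 <- gx - array(interp3(v1, gx, gy, gz), shape) - cc$x
    r2 <- gy - array(interp3(v2, gx, gy, gz), shape) - cc$y
    r3 <- gz - array(interp3(v3, gx, gy, gz), shape) - cc$z
    if (max(abs(r1), abs(r2), abs(r3)) < 1e-6) break
    # Jacobian of f_v at g: J = I - Dv(g)
    J <- lapply(1:3, function(i) lapply(1:3, function(j) {
      (i == j) - array(interp3(dv[[i]][[j]], gx, gy, gz), shape)
    }))
    c11 <- J[[2]][[2]] * J[[3]][[3]] - J[[2]][[3]] * J[[3]][[2]]
    c12 <- J[[2]][[3]] * J[[3]][[1]] - J[[2]][[1]] * J[[3]][[3]]
    c13 <- J[[2]][[1]] * J[[3]][[2]] - J[[2]][[2]] * J[[3]][[1]]
    detJ <- J[[1]][[1]] * c11 + J[[1]][[2]] * c12 + J[[1]][[3]] * c13
    detJ[abs(detJ) < 1e-3] <- sign(detJ[abs(detJ) < 1e-3] + 1e-12) * 1e-3
    # inverse via adjugate rows
    a11 <- c11; a21 <- c12; a31 <- c13
    a12 <- J[[1]][[3]] * J[[3]][[2]] - J[[1]][[2]] * J[[3]][[3]]
    a22 <- J[[1]][[1]] * J[[3]][[3]] - J[[1]][[3]] * J[[3]][[1]]
    a32 <- J[[1]][[2]] * J[[3]][[1]] - J[[1]][[1]] * J[[3]][[2]]
    a13 <- J[[1]][[2]] * J[[2]][[3]] - J[[1]][[3]] * J[[2]][[2]]
    a23 <- J[[1]][[3]] * J[[2]][[1]] - J[[1]][[1]] * J[[2]][[3]]
    a33 <- J[[1]][[1]] * J[[2]][[2]] - J[[1]][[2]] * J[[2]][[1]]
    step <- 0.9
    gx <- gx - step * (a11 * r1 + a12 * r2 + a13 * r3) / detJ
    gy <- gy - step * (a21 * r1 + a22 * r2 + a23 * r3) / detJ
    gz <- gz - step * (a31 * r1 + a32 * r2 + a33 * r3) / detJ
    gx <- pmin(pmax(gx, 1), shape[1])
    gy <- pmin(pmax(gy, 1), shape[2])
    gz <- pmin(pmax(gz, 1), shape[3])
  }
  # I_v(y) = (I0/det(Df_v))(g(y)): uses the same forward-map determinant as
  # the MP constraint, so the round trip is consistent with the solver
  Q <- I0$data / pmax(detf, 1e-3)
  img <- array(interp3(Q, gx, gy, gz), shape)
  img[img < 0] <- 0
  mass <- sum(img)
  if (mass <= 0)
    tb_stop("tb_inversion_failure", "synthesized image has no mass")
  if (abs(mass - sum(I0$data)) / sum(I0$data) > 0.01 * 5)
    warning(sprintf("inversion changed total mass by %.1f%%",
                    100 * abs(mass - sum(I0$data)) / sum(I0$data)))
  out <- vol_img(img / mass, spacing = I0$spacing, origin = I0$origin,
                 units = "normalized-mass")
  out
}
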