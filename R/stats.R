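# Transport-space statistical modeling: PCA, penalized LDA, single-outcome
# CCA, covariate augmentation, repeated-split validation, metrics, power.

#' Principal components of an embedding matrix
#'
#' Centered PCA retaining the smallest number of directions whose cumulative
#' explained variance reaches `var_frac` (the dimensionality of transport
#' embeddings greatly exceeds the number of subjects, so all computation runs
#' through the thin SVD).
#'
#' @param X numeric matrix, one row per subject (embeddings or scores).
#' @param var_frac fraction of variance to retain, in (0, 1].
#' @return An object of class `tbm_pca` with `center`, `rotation` (columns =
#'   components), `sdev`, `explained` (fractions), `n_retained`.
#' @export
fit_pca <- function(X, var_frac = 0.95) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) tb_stop("tb_invalid_parameter", "PCA needs >= 2 rows")
  if (var_frac <= 0 || var_frac > 1)
    tb_stop("tb_invalid_parameter", "var_frac must be in (0, 1]")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc)
  pos <- sv$d > max(sv$d[1], 0) * 1e-10
  if (!any(pos) || sv$d[1] == 0)
    tb_stop("tb_degenerate_data", "data has zero variance")
  d <- sv$d[pos]
  rot <- sv$v[, pos, drop = FALSE]
  vars <- d^2 / (n - 1)
  expl <- vars / sum(vars)
  n_retained <- which(cumsum(expl) >= var_frac - 1e-12)[1]
  structure(list(center = ctr, rotation = rot, sdev = sqrt(vars),
                 explained = expl, n_retained = n_retained,
                 var_frac = var_frac),
            class = "tbm_pca")
}

#' @export
print.tbm_pca <- function(x, ...) {
  cat(sprintf("<tbm_pca> %d retained of %d components (%.1f%% variance)\n",
              x$n_retained, length(x$sdev),
              100 * sum(x$explained[seq_len(x$n_retained)])))
  invisible(x)
}

#' Project rows into the retained principal subspace
#'
#' @param object a `tbm_pca`.
#' @param newdata matrix of rows on the same feature grid.
#' @param ... unused.
#' @return Score matrix with `n_retained` columns.
#' @export
predict.tbm_pca <- function(object, newdata, ...) {
  nd <- sweep(as.matrix(newdata), 2, object$center)
  nd %*% object$rotation[, seq_len(object$n_retained), drop = FALSE]
}

#' Map reduced-space points back to the embedding space
#'
#' @param pca a `tbm_pca`.
#' @param scores matrix (or vector) of reduced coordinates.
#' @return Matrix of embedding-space rows.
#' @export
pca_backproject <- function(pca, scores) {
  s <- matrix(scores, ncol = pca$n_retained)
  sweep(s %*% t(pca$rotation[, seq_len(pca$n_retained), drop = FALSE]),
        2, pca$center, `+`)
}

# Rank (Mann-Whitney) AUROC with midrank ties.
auroc_rank <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0)
    tb_stop("tb_degenerate_data", "AUROC needs both classes present")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Crossing point of two equal-prior Gaussian densities, between the means
# when such a root exists, else the midpoint.
gaussian_crossing <- function(m0, s0, m1, s1) {
  s0 <- max(s0, 1e-12); s1 <- max(s1, 1e-12)
  if (abs(s0 - s1) < 1e-9 * max(s0, s1)) return((m0 + m1) / 2)
  a <- 1 / s0^2 - 1 / s1^2
  b <- -2 * (m0 / s0^2 - m1 / s1^2)
  cc <- m0^2 / s0^2 - m1^2 / s1^2 - 2 * log(s1 / s0)
  disc <- b^2 - 4 * a * cc
  if (disc < 0) return((m0 + m1) / 2)
  roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  lo <- min(m0, m1); hi <- max(m0, m1)
  inside <- roots[roots >= lo & roots <= hi]
  if (length(inside)) inside[1] else (m0 + m1) / 2
}

#' Penalized linear discriminant direction for a binary outcome
#'
#' Fisher discriminant with a ridge-penalized within-class scatter,
#' `w = (S_W + lambda I)^-1 (m1 - m0)` (the penalty is scaled by the mean
#' diagonal of `S_W` so the grid is scale-free). The penalty is chosen by
#' inner-split validation AUROC over `lambda_grid`; the decision threshold is
#' the equal-prior crossing of the two projected class Gaussians.
#'
#' @param Xw reduced score matrix (rows = subjects).
#' @param labels logical (or coercible) outcome, both classes present with
#'   >= 2 members each.
#' @param lambda_grid candidate ridge penalties (relative units).
#' @param n_inner number of inner validation splits for penalty choice.
#' @return An object of class `tbm_plda` with unit `direction`, `lambda`,
#'   `threshold`, projected class means/SDs.
#' @export
fit_plda <- function(Xw, labels, lambda_grid = 10^seq(-3, 3), n_inner = 5) {
  Xw <- as.matrix(Xw)
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2)
    tb_stop("tb_degenerate_data", "pLDA needs both classes")
  if (min(sum(labels), sum(!labels)) < 2)
    tb_stop("tb_degenerate_data", "each class needs >= 2 members")
  fit_dir <- function(X, y, lambda) {
    m0 <- colMeans(X[!y, , drop = FALSE])
    m1 <- colMeans(X[y, , drop = FALSE])
    X0 <- sweep(X[!y, , drop = FALSE], 2, m0)
    X1 <- sweep(X[y, , drop = FALSE], 2, m1)
    Sw <- crossprod(X0) + crossprod(X1)
    scale <- mean(diag(Sw))
    if (scale <= 0) scale <- 1
    w <- solve(Sw + lambda * scale * diag(ncol(X)), m1 - m0)
    w / sqrt(sum(w^2))
  }
  lambda <- lambda_grid[1]
  if (length(lambda_grid) > 1 && min(sum(labels), sum(!labels)) >= 4) {
    perf <- with_seed(104729L, {
      vapply(lambda_grid, function(l) {
        mean(vapply(seq_len(n_inner), function(s) {
          idx1 <- which(labels); idx0 <- which(!labels)
          tr <- c(sample(idx1, ceiling(length(idx1) / 2)),
                  sample(idx0, ceiling(length(idx0) / 2)))
          te <- setdiff(seq_along(labels), tr)
          if (length(unique(labels[te])) < 2) return(NA_real_)
          w <- tryCatch(fit_dir(Xw[tr, , drop = FALSE], labels[tr], l),
                        error = function(e) NULL)
          if (is.null(w)) return(NA_real_)
          auroc_rank(Xw[te, , drop = FALSE] %*% w, labels[te])
        }, 0), na.rm = TRUE)
      }, 0)
    })
    lambda <- lambda_grid[which.max(perf)]
  }
  w <- fit_dir(Xw, labels, lambda)
  proj <- drop(Xw %*% w)
  if (mean(proj[labels]) < mean(proj[!labels])) {
    w <- -w
    proj <- -proj
  }
  m0 <- mean(proj[!labels]); s0 <- sd(proj[!labels])
  m1 <- mean(proj[labels]); s1 <- sd(proj[labels])
  structure(list(direction = w, lambda = lambda,
                 threshold = gaussian_crossing(m0, s0, m1, s1),
                 proj_mean = c(no = m0, yes = m1),
                 proj_sd = c(no = s0, yes = s1)),
            class = "tbm_plda")
}

#' @export
print.tbm_plda <- function(x, ...) {
  cat(sprintf("<tbm_plda> %d-dim direction, lambda = %g, threshold = %.4f\n",
              length(x$direction), x$lambda, x$threshold))
  invisible(x)
}

#' @export
coef.tbm_plda <- function(object, ...) object$direction

#' @param object a `tbm_plda`.
#' @param newdata reduced score matrix.
#' @param type `"score"` (projection) or `"class"`.
#' @param ... unused.
#' @rdname fit_plda
#' @export
predict.tbm_plda <- function(object, newdata, type = c("score", "class"),
                             ...) {
  type <- match.arg(type)
  s <- drop(as.matrix(newdata) %*% object$direction)
  if (type == "score") s else s >= object$threshold
}

#' Most-correlated direction for a continuous outcome
#'
#' With a single outcome, canonical correlation reduces to the direction
#' maximizing the Pearson correlation between the projected scores and the
#' outcome - the normalized least-squares direction
#' `Cov(X)^-1 Cov(X, y)`.
#'
#' @param Xw reduced score matrix.
#' @param y continuous outcome with positive variance.
#' @return An object of class `tbm_cca` with unit `direction` and
#'   `train_cor`.
#' @export
fit_cca <- function(Xw, y) {
  Xw <- as.matrix(Xw)
  if (var(y) <= 0) tb_stop("tb_degenerate_data", "outcome has no variance")
  yc <- y - mean(y)
  Xc <- sweep(Xw, 2, colMeans(Xw))
  S <- crossprod(Xc)
  w <- solve(S + 1e-10 * mean(diag(S)) * diag(ncol(Xw)), crossprod(Xc, yc))
  w <- drop(w)
  w <- w / sqrt(sum(w^2))
  r <- cor(drop(Xw %*% w), y)
  if (r < 0) {
    w <- -w
    r <- -r
  }
  structure(list(direction = w, train_cor = r), class = "tbm_cca")
}

#' @export
print.tbm_cca <- function(x, ...) {
  cat(sprintf("<tbm_cca> %d-dim direction, training correlation %.3f\n",
              length(x$direction), x$train_cor))
  invisible(x)
}

#' @export
coef.tbm_cca <- function(object, ...) object$direction

#' @param object a `tbm_cca`.
#' @param newdata reduced score matrix.
#' @param ... unused.
#' @rdname fit_cca
#' @export
predict.tbm_cca <- function(object, newdata, ...) {
  drop(as.matrix(newdata) %*% object$direction)
}

#' Lesion location relative to the template center
#'
#' @param m a [seg_mask()].
#' @param template_center world mm of the template center of mass.
#' @return Numeric length 3 (mm offsets).
#' @export
location_vector <- function(m, template_center) {
  if (sum(m$data) == 0) tb_stop("tb_empty_lesion", "mask is empty")
  center_of_mass(m) - template_center
}

# Integer-voxel shift with zero fill; errors if nonzero voxels would leave
# the grid.
shift_zero <- function(a, by) {
  d <- dim(a)
  out <- a
  for (ax in 1:3) {
    b <- by[ax]
    if (b == 0) next
    n <- d[ax]
    src <- seq_len(n) - b
    ok <- src >= 1 & src <= n
    # content at source index j lands at j + b; sources pushed off the grid
    # must be empty
    if (abs(b) >= n) {
      if (any(out != 0))
        tb_stop("tb_out_of_bounds", "translation would clip the lesion")
      next
    }
    drop_idx <- if (b > 0) seq(n - b + 1, n) else seq_len(-b)
    lost <- switch(ax,
      out[drop_idx, , , drop = FALSE],
      out[, drop_idx, , drop = FALSE],
      out[, , drop_idx, drop = FALSE])
    if (any(lost != 0))
      tb_stop("tb_out_of_bounds", "translation would clip the lesion")
    tmp <- array(0, dim = d)
    if (any(ok)) {
      w <- which(ok)
      if (ax == 1) tmp[w, , ] <- out[src[w], , , drop = FALSE]
      if (ax == 2) tmp[, w, ] <- out[, src[w], , drop = FALSE]
      if (ax == 3) tmp[, , w] <- out[, , src[w], drop = FALSE]
    }
    out <- tmp
  }
  out
}

#' Translate a lesion so its center of mass sits at the template center
#'
#' Makes the downstream transport maps location-invariant; the removed
#' translation (mm) is returned so it can re-enter the model as a spatial
#' covariate. The shift is rounded to whole voxels so masks stay binary and
#' the operation is exactly reversible.
#'
#' @param v a [vol_img()].
#' @param m its [seg_mask()].
#' @param template_center world mm of the template center of mass.
#' @return List with `image`, `mask`, `translation` (mm, the pre-shift
#'   offset).
#' @export
make_location_invariant <- function(v, m, template_center) {
  stopifnot_same_grid(v, m)
  t_mm <- location_vector(m, template_center)
  shift_vox <- round(t_mm / v$spacing)
  v$data <- shift_zero(v$data, -shift_vox)
  m$data <- shift_zero(m$data, -shift_vox)
  list(image = v, mask = m, translation = t_mm)
}

#' Concatenate transport scores with spatial and clinical covariates
#'
#' Builds the augmented feature row-block `[w_k | x,y,z | clinical]` and
#' z-scores each column. Standardization parameters are fitted on the
#' training block and must be reused (via `params`) to transform validation
#' or test rows.
#'
#' @param scores reduced transport scores (matrix, rows = subjects).
#' @param translation matrix of per-subject translation coordinates (mm).
#' @param clinical matrix or data.frame of clinical covariates
#'   (age, sex, INR, IVH score); missing values raise an error.
#' @param params `NULL` to fit standardization on these rows (training), or
#'   the `params` element of a previous call (test).
#' @return List with `a` (standardized feature matrix) and `params`.
#' @export
augment_features <- function(scores, translation, clinical, params = NULL) {
  blocks <- cbind(as.matrix(scores), as.matrix(translation),
                  data.matrix(clinical))
  if (any(is.na(blocks)))
    tb_stop("tb_missing_data", "missing covariate values; no silent imputation")
  if (is.null(params)) {
    mu <- colMeans(blocks)
    sg <- apply(blocks, 2, sd)
    sg[sg < 1e-12] <- 1
    params <- list(mean = mu, sd = sg)
  }
  a <- sweep(sweep(blocks, 2, params$mean), 2, params$sd, `/`)
  list(a = a, params = params)
}

#' Repeated 60/40 split plan
#'
#' @param n_repeats number of random splits (the study protocol uses 1000).
#' @param train_frac fraction of subjects in the training part.
#' @param seed master seed; per-repeat seeds are derived from it.
#' @return An object of class `tbm_split_plan`.
#' @export
split_plan <- function(n_repeats = 1000, train_frac = 0.6, seed = 1L) {
  stopifnot(n_repeats >= 1, train_frac > 0, train_frac < 1)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, n_repeats))
  structure(list(n_repeats = as.integer(n_repeats), train_frac = train_frac,
                 seed = as.integer(seed), repeat_seeds = seeds),
            class = "tbm_split_plan")
}

#' Classification metrics at a decision threshold
#'
#' AUROC by the rank (Mann-Whitney) formula with midrank ties; confusion
#' metrics with positives called at `score >= threshold`.
#'
#' @param scores numeric classifier scores.
#' @param labels logical (or coercible) truth.
#' @param threshold decision threshold.
#' @return Named list: `auroc`, `accuracy`, `sensitivity`, `specificity`,
#'   `ppv`, `npv`.
#' @export
classification_metrics <- function(scores, labels, threshold) {
  labels <- as.logical(labels)
  auc <- auroc_rank(scores, labels)
  pred <- scores >= threshold
  tp <- sum(pred & labels); fn <- sum(!pred & labels)
  tn <- sum(!pred & !labels); fp <- sum(pred & !labels)
  list(auroc = auc,
       accuracy = (tp + tn) / length(labels),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
}

#' Combine p-values across repeated splits by Fisher's method
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return Combined p-value from the chi-squared statistic `-2 sum log p` on
#'   `2k` degrees of freedom.
#' @export
fisher_combine <- function(pvalues) {
  if (any(pvalues <= 0) || any(pvalues > 1))
    tb_stop("tb_invalid_parameter", "p-values must lie in (0, 1]")
  stat <- -2 * sum(log(pvalues))
  pchisq(stat, df = 2 * length(pvalues), lower.tail = FALSE)
}

#' Power of an AUC test (Hanley-McNeil approximation)
#'
#' Power to detect `auc_alt` against `auc_null` with a normal test statistic
#' whose standard errors come from the Hanley-McNeil variance approximation
#' `V(A) = (A(1-A) + (n1-1)(Q1-A^2) + (n2-1)(Q2-A^2)) / (n1 n2)` with
#' `Q1 = A/(2-A)`, `Q2 = 2A^2/(1+A)`.
#'
#' @param n total number of subjects.
#' @param prevalence positive-class fraction in (0, 1).
#' @param auc_alt AUC under the alternative, in `[0.5, 1]`.
#' @param auc_null AUC under the null.
#' @param alpha significance level.
#' @param sided `"two"` or `"one"`.
#' @return Power in `[0, 1]`.
#' @export
auc_power <- function(n, prevalence, auc_alt, auc_null = 0.5, alpha = 0.05,
                      sided = c("two", "one")) {
  sided <- match.arg(sided)
  if (prevalence <= 0 || prevalence >= 1)
    tb_stop("tb_invalid_parameter", "prevalence must be in (0, 1)")
  if (auc_alt < 0.5 || auc_alt > 1)
    tb_stop("tb_invalid_parameter", "auc_alt must be in [0.5, 1]")
  n1 <- round(n * prevalence)
  n0 <- n - n1
  if (n1 < 2 || n0 < 2)
    tb_stop("tb_degenerate_data", "degenerate group sizes")
  hm_var <- function(A) {
    Q1 <- A / (2 - A)
    Q2 <- 2 * A^2 / (1 + A)
    (A * (1 - A) + (n1 - 1) * (Q1 - A^2) + (n0 - 1) * (Q2 - A^2)) / (n1 * n0)
  }
  se0 <- sqrt(hm_var(auc_null))
  se1 <- sqrt(hm_var(auc_alt))
  delta <- auc_alt - auc_null
  z <- qnorm(1 - alpha / ifelse(sided == "two", 2, 1))
  pnorm((delta - z * se0) / se1) + pnorm((-delta - z * se0) / se1)
}

#' Monte-Carlo cross-check of the AUC power calculation
#'
#' Simulates binormal scores (negatives `N(0,1)`, positives `N(mu,1)` with
#' `mu = sqrt(2) qnorm(auc_alt)`), computes the rank AUC per replicate, and
#' tests it against `auc_null` with the Hanley-McNeil null standard error.
#'
#' @inheritParams auc_power
#' @param reps Monte-Carlo replicates.
#' @param seed RNG seed.
#' @return Rejection fraction (empirical power).
#' @export
auc_power_mc <- function(n, prevalence, auc_alt, auc_null = 0.5,
                         alpha = 0.05, sided = c("two", "one"),
                         reps = 10000, seed = 1L) {
  sided <- match.arg(sided)
  n1 <- round(n * prevalence)
  n0 <- n - n1
  mu <- sqrt(2) * qnorm(auc_alt)
  hm_var0 <- {
    A <- auc_null
    Q1 <- A / (2 - A); Q2 <- 2 * A^2 / (1 + A)
    (A * (1 - A) + (n1 - 1) * (Q1 - A^2) + (n0 - 1) * (Q2 - A^2)) / (n1 * n0)
  }
  se0 <- sqrt(hm_var0)
  zcrit <- qnorm(1 - alpha / ifelse(sided == "two", 2, 1))
  lab <- c(rep(FALSE, n0), rep(TRUE, n1))
  with_seed(seed, {
    rej <- vapply(seq_len(reps), function(i) {
      x <- c(rnorm(n0), rnorm(n1, mu))
      A <- auroc_rank(x, lab)
      z <- (A - auc_null) / se0
      if (sided == "two") abs(z) > zcrit else z > zcrit
    }, TRUE)
    mean(rej)
  })
}

#' Repeated stratified 60/40 validation of transport-space models
#'
#' Per repeat: split subjects (stratified by label for classification), fit
#' PCA on the training rows, optionally augment with standardized covariates
#' (training statistics only), fit the model (pLDA or single-outcome CCA),
#' and evaluate on the held-out rows. Results are aggregated as means with
#' percentile 95% confidence intervals; per-repeat p-values (projection
#' t-test for pLDA, correlation test for CCA) are combined by Fisher's
#' method.
#'
#' @param X feature matrix (rows = subjects), e.g. LOT embeddings.
#' @param outcome logical labels (pLDA) or numeric growth (CCA).
#' @param plan a [split_plan()].
#' @param model `"plda"` or `"cca"`.
#' @param covariates optional matrix of unstandardized covariate columns
#'   (e.g. translation mm + clinical) appended after PCA.
#' @param var_frac PCA variance retention.
#' @param lambda_grid passed to [fit_plda()].
#' @return An object of class `tbm_metrics`: `per_repeat` data frame,
#'   `summary` (mean and 95% CI per metric), `combined_p`.
#' @export
run_repeated_splits <- function(X, outcome, plan = split_plan(25),
                                model = c("plda", "cca"), covariates = NULL,
                                var_frac = 0.95,
                                lambda_grid = 10^seq(-3, 3)) {
  model <- match.arg(model)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 10) tb_stop("tb_invalid_parameter", "need >= 10 subjects")
  if (!is.null(covariates)) covariates <- as.matrix(covariates)
  rows <- vector("list", plan$n_repeats)
  redraws <- 0L
  for (r in seq_len(plan$n_repeats)) {
    sp <- with_seed(plan$repeat_seeds[r], {
      for (attempt in 1:10) {
        if (model == "plda") {
          lab <- as.logical(outcome)
          tr <- c(sample(which(lab), round(sum(lab) * plan$train_frac)),
                  sample(which(!lab), round(sum(!lab) * plan$train_frac)))
        } else {
          tr <- sample(n, round(n * plan$train_frac))
        }
        te <- setdiff(seq_len(n), tr)
        ok <- model == "cca" ||
          (length(unique(outcome[tr])) == 2 &&
             length(unique(outcome[te])) == 2)
        if (ok) break
        redraws <- redraws + 1L
      }
      list(tr = tr, te = te)
    })
    tr <- sp$tr; te <- sp$te
    pca <- fit_pca(X[tr, , drop = FALSE], var_frac)
    str <- predict(pca, X[tr, , drop = FALSE])
    ste <- predict(pca, X[te, , drop = FALSE])
    if (!is.null(covariates)) {
      atr <- augment_features(str, covariates[tr, , drop = FALSE][, 0],
                              covariates[tr, , drop = FALSE])
      ate <- augment_features(ste, covariates[te, , drop = FALSE][, 0],
                              covariates[te, , drop = FALSE],
                              params = atr$params)
      str <- atr$a; ste <- ate$a
    }
    if (model == "plda") {
      fit <- fit_plda(str, outcome[tr], lambda_grid)
      sc <- predict(fit, ste)
      met <- classification_metrics(sc, outcome[te], fit$threshold)
      pv <- tryCatch(t.test(sc[as.logical(outcome[te])],
                            sc[!as.logical(outcome[te])])$p.value,
                     error = function(e) NA_real_)
      rows[[r]] <- data.frame(repeat_id = r, auroc = met$auroc,
                              accuracy = met$accuracy,
                              sensitivity = met$sensitivity,
                              specificity = met$specificity,
                              ppv = met$ppv, npv = met$npv, p = pv)
    } else {
      fit <- fit_cca(str, outcome[tr])
      sc <- predict(fit, ste)
      ct <- tryCatch(cor.test(sc, outcome[te]),
                     error = function(e) list(estimate = NA, p.value = NA))
      rows[[r]] <- data.frame(repeat_id = r, cc = unname(ct$estimate),
                              p = ct$p.value)
    }
  }
  per <- do.call(rbind, rows)
  mets <- setdiff(names(per), c("repeat_id", "p"))
  summ <- lapply(mets, function(mname) {
    v <- per[[mname]]
    c(mean = mean(v, na.rm = TRUE),
      lo = unname(quantile(v, 0.025, na.rm = TRUE)),
      hi = unname(quantile(v, 0.975, na.rm = TRUE)))
  })
  names(summ) <- mets
  pv <- per$p[!is.na(per$p)]
  pv[pv <= 0] <- .Machine$double.xmin
  structure(list(per_repeat = per, summary = summ,
                 combined_p = if (length(pv)) fisher_combine(pv) else NA_real_,
                 model = model, plan = plan, redraws = redraws),
            class = "tbm_metrics")
}

#' @export
print.tbm_metrics <- function(x, ...) {
  cat(sprintf("<tbm_metrics> %s over %d repeats\n", x$model,
              nrow(x$per_repeat)))
  for (mname in names(x$summary)) {
    s <- x$summary[[mname]]
    cat(sprintf("  %-12s %.3f [%.3f, %.3f]\n", mname, s["mean"], s["lo"],
                s["hi"]))
  }
  cat(sprintf("  combined p (Fisher): %.3g\n", x$combined_p))
  invisible(x)
}
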