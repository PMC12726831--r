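#' Default end-to-end pipeline configuration
#'
#' Desk-scale profile: 32^3 grid at 2 mm spacing, 60 subjects, 3-level
#' solver. Every field can be overridden through the `config` argument of
#' [run_pipeline()] (lists are merged recursively).
#'
#' @return Nested list of stage settings.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    cohort = list(n = 60, shape = c(32, 32, 32), spacing = 2,
                  effect_weights = c(size = 4, periph = 1.5),
                  noise_sd = 2, target_prevalence = 0.33),
    model = list(outcome = "both", covariates = "none", var_frac = 0.95,
                 template_iters = 2, max_iters = 25),
    evaluate = list(n_repeats = 10, train_frac = 0.6),
    visualize = list(which = "plda", sigmas = c(-2, -1, 0, 1, 2),
                     plane = "axial"),
    power = list(n = 170, prevalence = 0.25, auc_alt = 0.7, auc_null = 0.5,
                 alpha = 0.05),
    write_cohort = FALSE
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Run the simulate -> fit -> evaluate -> visualize -> power pipeline
#'
#' Executes the full study workflow on a synthetic cohort and writes every
#' artifact into `out_dir`: the config snapshot (YAML), the template
#' (NIfTI), per-repeat and summary metrics (CSV/JSON), the traversal images
#' (NIfTI) with overlay renderings (PNG), and the power calculation (JSON).
#' Reruns with an identical config reproduce the metrics exactly.
#'
#' @param config named list (merged over [default_pipeline_config()]) or a
#'   path to a YAML file with the same structure.
#' @param out_dir output directory, created if needed.
#' @param stages character subset of
#'   `c("simulate","fit","evaluate","visualize","power")`.
#' @param verbose print stage progress.
#' @return Invisibly, a list with the cohort, fit, metrics, traversal and
#'   power results.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("tbm_run_"),
                         stages = c("simulate", "fit", "evaluate",
                                    "visualize", "power"),
                         verbose = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_pipeline_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  say <- function(stage, ...) {
    if (verbose) message(sprintf("[%s seed=%d] %s", stage, cfg$seed,
                                 sprintf(...)))
  }
  out <- list(config = cfg, out_dir = out_dir)

  if ("simulate" %in% stages) {
    say("simulate", "generating %d subjects", cfg$cohort$n)
    ew <- unlist(cfg$cohort$effect_weights)
    cs <- cohort_spec(n = cfg$cohort$n,
                      grid = make_grid(unlist(cfg$cohort$shape),
                                       cfg$cohort$spacing),
                      effect_weights = ew,
                      noise_sd = cfg$cohort$noise_sd,
                      target_prevalence = cfg$cohort$target_prevalence,
                      seed = cfg$seed)
    out$cohort <- make_cohort(cs)
    if (isTRUE(cfg$write_cohort))
      write_cohort(out$cohort, file.path(out_dir, "cohort"))
    ft <- feature_table(out$cohort)
    write.csv(ft, file.path(out_dir, "features.csv"), row.names = FALSE)
  }

  if ("fit" %in% stages) {
    if (is.null(out$cohort)) tb_stop("tb_invalid_parameter",
                                     "fit stage requires the simulate stage")
    say("fit", "fitting tbm model (covariates: %s)", cfg$model$covariates)
    out$fit <- tbm(out$cohort, outcome = cfg$model$outcome,
                   covariates = cfg$model$covariates,
                   var_frac = cfg$model$var_frac,
                   solver = solver_config(max_iters = cfg$model$max_iters),
                   template_iters = cfg$model$template_iters,
                   verbose = verbose)
    write_volume(out$fit$template$image,
                 file.path(out_dir, "template.nii.gz"))
  }

  if ("evaluate" %in% stages) {
    if (is.null(out$fit)) tb_stop("tb_invalid_parameter",
                                  "evaluate stage requires the fit stage")
    say("evaluate", "%d repeated splits", cfg$evaluate$n_repeats)
    plan <- split_plan(cfg$evaluate$n_repeats, cfg$evaluate$train_frac,
                       seed = cfg$seed)
    covmat <- out$fit$covmat
    out$metrics_expansion <- run_repeated_splits(
      out$fit$embeddings, out$fit$labels, plan, model = "plda",
      covariates = covmat, var_frac = cfg$model$var_frac)
    out$metrics_growth <- run_repeated_splits(
      out$fit$embeddings, out$fit$growth, plan, model = "cca",
      covariates = covmat, var_frac = cfg$model$var_frac)
    write.csv(out$metrics_expansion$per_repeat,
              file.path(out_dir, "metrics_expansion.csv"), row.names = FALSE)
    write.csv(out$metrics_growth$per_repeat,
              file.path(out_dir, "metrics_growth.csv"), row.names = FALSE)
    summ <- list(
      expansion = c(lapply(out$metrics_expansion$summary, as.list),
                    combined_p = out$metrics_expansion$combined_p),
      growth = c(lapply(out$metrics_growth$summary, as.list),
                 combined_p = out$metrics_growth$combined_p))
    jsonlite::write_json(summ, file.path(out_dir, "metrics_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  if ("visualize" %in% stages) {
    if (is.null(out$fit)) tb_stop("tb_invalid_parameter",
                                  "visualize stage requires the fit stage")
    say("visualize", "traversing %s direction", cfg$visualize$which)
    trav <- traverse_direction(out$fit, which = cfg$visualize$which,
                               sigmas = cfg$visualize$sigmas)
    out$traversal <- trav
    slice <- round(com_voxel(out$fit$template$image$data)[3])
    for (i in seq_along(trav$sigmas)) {
      if (is.null(trav$images[[i]])) next
      tag <- sprintf("sigma_%+03.1f", trav$sigmas[i])
      write_volume(trav$images[[i]],
                   file.path(out_dir, paste0("traversal_", tag, ".nii.gz")))
      ov <- overlay_render(out$fit$template$image, trav$images[[i]],
                           plane = cfg$visualize$plane, slice_index = slice)
      png(file.path(out_dir, paste0("overlay_", tag, ".png")),
          width = 64 * ncol(ov$rgb) / nrow(ov$rgb) * 4, height = 64 * 4)
      op <- par(mar = c(0, 0, 0, 0))
      plot.new(); plot.window(c(0, 1), c(0, 1))
      rasterImage(ov$rgb, 0, 0, 1, 1)
      par(op)
      dev.off()
    }
  }

  if ("power" %in% stages) {
    say("power", "AUC power calculation")
    pw <- cfg$power
    out$power <- list(
      closed_form = auc_power(pw$n, pw$prevalence, pw$auc_alt, pw$auc_null,
                              pw$alpha),
      monte_carlo = auc_power_mc(pw$n, pw$prevalence, pw$auc_alt,
                                 pw$auc_null, pw$alpha, reps = 2000,
                                 seed = cfg$seed))
    jsonlite::write_json(out$power, file.path(out_dir, "power.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  invisible(out)
}
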