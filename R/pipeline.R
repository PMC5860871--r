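#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis in one plain list
#' that serializes losslessly to JSON (see [config_to_json()]).  All
#' randomness derives from the single `seed`.
#'
#' @param n_control,n_dyslexic,tau_control_s,tau_dyslexic_s,between_subject_sd,a_mean,b_mean,a_sd,b_sd
#'   Cohort parameters, see [make_group_cohort()].
#' @param sigma,drift_amp,spatial_fwhm_mm Noise parameters, see
#'   [noise_spec()].
#' @param design Named list of [study_design()] arguments (defaults
#'   apply for the rest).
#' @param highpass_cycles High-pass cutoff (cycles/run); `NULL`
#'   disables filtering.
#' @param zscore,smooth_fwhm_mm Preprocessing switches.
#' @param fdr_q Task-responsiveness FDR level.
#' @param tau_bounds,n_grid Decay-fit settings.
#' @param voxel_alpha Cluster-forming voxelwise threshold.
#' @param fwe_alpha Family-wise error target for cluster correction.
#' @param mc_iter Monte-Carlo iterations for the extent threshold.
#' @param connectivity Cluster adjacency (6, 18, 26).
#' @param mc_field Null-map model for the extent threshold
#'   (`"rank"`, the calibrated default for Mann-Whitney maps, or the
#'   classic `"gaussian"`); see
#'   [monte_carlo_cluster_threshold()].
#' @param seed Master seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(n_control = 19, n_dyslexic = 20,
                            tau_control_s = 10, tau_dyslexic_s = 5,
                            between_subject_sd = 0.2,
                            a_mean = 0.5, b_mean = 1, a_sd = 0.05, b_sd = 0.1,
                            sigma = 0.3, drift_amp = 1, spatial_fwhm_mm = 0,
                            design = list(),
                            highpass_cycles = 3, zscore = TRUE,
                            smooth_fwhm_mm = 4,
                            fdr_q = 0.001,
                            tau_bounds = c(0.1, 60), n_grid = 50,
                            voxel_alpha = 0.05, fwe_alpha = 0.05,
                            mc_iter = 1000, connectivity = 26,
                            mc_field = "rank",
                            seed = 1) {
  stopifnot(fdr_q > 0, fdr_q < 1, voxel_alpha > 0, voxel_alpha < 1,
            fwe_alpha > 0, fwe_alpha <= 1, mc_iter >= 100,
            connectivity %in% c(6, 18, 26),
            mc_field %in% c("gaussian", "rank"))
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Serialize / restore a pipeline configuration
#'
#' @param config A [pipeline_config()].
#' @param path JSON file path.
#' @return `config_from_json()` returns the restored `pipeline_config`.
#' @export
config_to_json <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname config_to_json
#' @export
config_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw$design)) raw$design <- list()
  if (length(raw$design)) raw$design <- as.list(raw$design)
  do.call(pipeline_config, raw)
}

#' Run the full synthetic-cohort analysis
#'
#' Executes generate, preprocess, GLM, task-voxel selection, voxelwise
#' decay fitting, group inference with Monte-Carlo cluster correction,
#' and ROI analysis, in order.  Rerunning with the same configuration
#' reproduces every output exactly.
#'
#' @param config A [pipeline_config()].
#' @param rois Optional named list of [roi_mask()]s to analyse.
#' @param out_dir Optional directory; when given, maps (NIfTI), tables
#'   (TSV) and a provenance JSON are written there.
#' @param verbose Print per-stage progress?
#' @return List of class `adapt_pipeline`: `cohort`, `beta_maps`,
#'   `task_mask`, `tau_maps`, `stat_map`, `k`, `clusters`, `roi_results`,
#'   `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config(), rois = NULL,
                         out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(...)
  timings <- c()
  tic <- function() Sys.time()
  toc <- function(t0, stage) {
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }

  t0 <- tic()
  design <- do.call(study_design, config$design)
  noise <- noise_spec(config$sigma, config$drift_amp, config$spatial_fwhm_mm)
  cohort <- make_group_cohort(
    n_control = config$n_control, n_dyslexic = config$n_dyslexic,
    tau_control_s = config$tau_control_s,
    tau_dyslexic_s = config$tau_dyslexic_s,
    between_subject_sd = config$between_subject_sd,
    a_mean = config$a_mean, b_mean = config$b_mean,
    a_sd = config$a_sd, b_sd = config$b_sd,
    noise = noise, design = design, seed = config$seed)
  toc(t0, "cohort")
  say("cohort: ", nrow(cohort$subjects), " subjects")

  t0 <- tic()
  dm <- build_design_matrix(design$schedules, design$tr_s, design$n_vols,
                            hrf = design$hrf,
                            drift_cycles = config$highpass_cycles)
  beta_maps <- analyse_cohort_subjects(cohort, dm, config)
  toc(t0, "glm")
  say("glm: ", length(beta_maps), " subject beta maps")

  t0 <- tic()
  task_mask <- select_task_responsive(beta_maps, q = config$fdr_q)
  n_task <- sum(task_mask)
  toc(t0, "task_selection")
  say("task-responsive voxels: ", n_task)

  grp <- cohort$subjects$group
  stat_map <- NULL; kthr <- NULL; clusters <- NULL; tau_maps <- NULL
  if (n_task >= 2) {
    t0 <- tic()
    tau_maps <- lapply(beta_maps, fit_decay_map, mask = task_mask,
                       tau_bounds = config$tau_bounds,
                       n_grid = config$n_grid)
    toc(t0, "decay_fit")
    t0 <- tic()
    stat_map <- voxelwise_group_map(tau_maps[grp == "control"],
                                    tau_maps[grp == "dyslexic"],
                                    mask = task_mask)
    kthr <- monte_carlo_cluster_threshold(
      task_mask, smoothness_fwhm_mm = config$smooth_fwhm_mm,
      voxel_size_mm = design$voxel_size_mm,
      voxel_alpha = config$voxel_alpha, fwe_alpha = config$fwe_alpha,
      n_iter = config$mc_iter, seed = config$seed + 1,
      connectivity = config$connectivity, field = config$mc_field,
      n1 = config$n_control, n2 = config$n_dyslexic)
    clusters <- cluster_corrected_map(stat_map, config$voxel_alpha,
                                      k = kthr,
                                      connectivity = config$connectivity)
    toc(t0, "group_inference")
    say("clusters surviving extent >= ", as.integer(kthr), ": ",
        sum(clusters$table$corrected_pass))
  } else {
    warning("fewer than 2 task-responsive voxels; voxelwise stages skipped")
  }

  roi_results <- NULL
  if (!is.null(rois)) {
    t0 <- tic()
    roi_results <- lapply(rois, function(roi)
      roi_group_compare(beta_maps, roi, grp,
                        tau_bounds = config$tau_bounds,
                        n_grid = config$n_grid))
    toc(t0, "roi")
  }

  prov <- list(config = unclass(config),
               package_version = as.character(utils::packageVersion("adaptdecay")),
               n_task_voxels = n_task,
               cluster_extent_threshold = if (!is.null(kthr)) as.integer(kthr),
               timings_s = as.list(timings),
               timestamp = format(Sys.time(), tz = "UTC"))
  out <- structure(
    list(cohort = cohort, beta_maps = beta_maps, task_mask = task_mask,
         tau_maps = tau_maps, stat_map = stat_map,
         k = if (!is.null(kthr)) as.integer(kthr), clusters = clusters,
         roi_results = roi_results, provenance = prov),
    class = "adapt_pipeline")
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

# simulate + preprocess + GLM for every subject, returning per-subject
# run-averaged beta maps; runs are realized one at a time and discarded
analyse_cohort_subjects <- function(cohort, dm, config) {
  n <- nrow(cohort$subjects)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    runs <- simulate_subject_runs(cohort, i)
    fits <- lapply(runs, function(run) {
      run <- preprocess_run(run, n_cycles = config$highpass_cycles,
                            zscore = config$zscore,
                            fwhm_mm = config$smooth_fwhm_mm)
      fit_glm(run, dm)
    })
    out[[i]] <- combine_beta_maps(fits)
  }
  names(out) <- cohort$subjects$subject
  out
}

#' @export
print.adapt_pipeline <- function(x, ...) {
  cat("Adaptation-decay pipeline result\n")
  print(x$cohort)
  cat(sprintf("  task-responsive voxels: %d\n", x$provenance$n_task_voxels))
  if (!is.null(x$clusters)) {
    cat(sprintf("  cluster extent threshold k = %d; surviving clusters: %d\n",
                x$k, sum(x$clusters$table$corrected_pass)))
  }
  if (!is.null(x$roi_results)) for (r in x$roi_results) print(r)
  invisible(x)
}

# write NIfTI maps, TSV tables and provenance JSON for a pipeline result
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  vs <- result$cohort$design$voxel_size_mm
  write_nifti(result$task_mask, file.path(out_dir, "task_mask.nii.gz"), vs)
  if (!is.null(result$stat_map)) {
    for (nm in c("z", "p", "r"))
      write_nifti(result$stat_map[[nm]],
                  file.path(out_dir, paste0("group_", nm, ".nii.gz")), vs)
    utils::write.table(result$clusters$table,
                       file.path(out_dir, "clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(result$roi_results)) {
    roi_tab <- do.call(rbind, lapply(result$roi_results, function(r)
      data.frame(roi = r$roi, U = r$U, z = r$z, p = r$p, r = r$r,
                 median_tau_group1 = r$median_tau[1],
                 median_tau_group2 = r$median_tau[2])))
    utils::write.table(roi_tab, file.path(out_dir, "roi_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(result$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
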