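#' Validate a pipeline configuration
#'
#' Central configuration for the end-to-end pipeline. All defaults equal the
#' analysis constants the package targets: Z threshold 0.275, N2 window
#' 280-340 ms and P3 window 350-570 ms at Cz, 128 s high-pass, voxel
#' p < 0.005 with cluster extent k = 20. A `sim` entry (a [sim_config]) is
#' required for synthetic cohorts. Validation happens before any stage runs.
#'
#' @param sim A [sim_config] template (per-subject seeds are derived from it).
#' @param n_subjects Number of synthetic subjects.
#' @param n_runs Runs per subject.
#' @param z_threshold Reliability threshold on |Z|.
#' @param erp_windows Named list with `N2` and `P3` latency windows (s).
#' @param electrode ERP extraction site.
#' @param glm_p,glm_k Voxelwise p and cluster extent of the group maps.
#' @param highpass_s First-level high-pass cutoff (s).
#' @param ica_max_iter Training-pass cap for the per-run ICA.
#' @param seed Master seed of the whole pipeline.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim, n_subjects = 8L, n_runs = 2L,
                            z_threshold = 0.275,
                            erp_windows = list(N2 = c(0.280, 0.340),
                                               P3 = c(0.350, 0.570)),
                            electrode = "Cz", glm_p = 0.005, glm_k = 20L,
                            highpass_s = 128, ica_max_iter = 512L, seed = 1L) {
  stopifnot(inherits(sim, "sim_config"))
  if (!is_scalar_num(z_threshold) || z_threshold <= 0)
    stopf("z_threshold must be a positive number")
  if (!is_scalar_num(glm_p) || glm_p <= 0 || glm_p >= 1)
    stopf("glm_p must lie in (0, 1)")
  if (glm_k < 1L) stopf("glm_k must be >= 1")
  for (w in erp_windows)
    if (length(w) != 2L || w[1] >= w[2]) stopf("malformed ERP window")
  cfg <- list(sim = sim, n_subjects = as.integer(n_subjects),
              n_runs = as.integer(n_runs), z_threshold = z_threshold,
              erp_windows = erp_windows, electrode = electrode,
              glm_p = glm_p, glm_k = as.integer(glm_k),
              highpass_s = highpass_s, ica_max_iter = as.integer(ica_max_iter),
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Analyze one synthetic run
#'
#' simulate -> ICA -> artifact-IC flagging -> IC epoching -> reliability
#' selection -> single-trial amplitudes -> EEG regressor -> first-level GLM.
#' Returns the per-run contrast image plus bookkeeping (selection, flags,
#' ground truth).
#'
#' @param run_cfg A [sim_config] for this run (seed already derived).
#' @param z_threshold,highpass_s,ica_max_iter See [pipeline_config()].
#' @param window_tag Window whose amplitudes drive the EEG regressor.
#' @return A list with `contrast` (3D beta array or `NULL` when the subject
#'   has no selected range for the window), `selection`, `flags`, `truth`.
#' @keywords internal
analyze_run <- function(run_cfg, z_threshold = 0.275, highpass_s = 128,
                        ica_max_iter = 512L, window_tag = "early") {
  events <- gen_paradigm(run_cfg)
  eeg <- gen_eeg(events, run_cfg)
  rec <- eeg$recording
  if (run_cfg$gradient)
    rec <- subtract_gradient_template(rec)
  dec <- fit_unmixing(rec, seed = derive_seed(run_cfg$seed, 77L),
                      max_iter = ica_max_iter)
  flags <- integer(0)
  if (run_cfg$bcg) {
    beats <- tryCatch(detect_artifact_events(rec, "ECG"), error = function(e) numeric(0))
    if (length(beats) >= 20L)
      flags <- union(flags, flag_artifact_ics(dec, rec, beats, n_null = 100L,
                                              seed = derive_seed(run_cfg$seed, 78L),
                                              reason = "bcg"))
  }
  if (run_cfg$blink) {
    blinks <- tryCatch(detect_artifact_events(rec, "EOG"), error = function(e) numeric(0))
    if (length(blinks) >= 20L)
      flags <- union(flags, flag_artifact_ics(dec, rec, blinks, n_null = 100L,
                                              seed = derive_seed(run_cfg$seed, 79L),
                                              reason = "blink"))
  }
  dec$artifact_flags <- flags
  act <- ic_activations(dec, rec)
  ep <- epoch_units(act, events, sfreq = rec$sfreq)
  sel <- select_ics(ep, mode = "nogo", z_threshold = z_threshold,
                    exclude = flags)
  contrast <- NULL
  amp <- NULL
  if (window_tag %in% sel$selection$window) {
    amp <- single_trial_amplitudes(ep, sel$selection, window_tag)
    bold <- gen_bold(events, eeg$truth, run_cfg)
    st <- scan_times(bold$volumes)
    onset_X <- build_onset_regressors(events, length(st), run_cfg$tr_s)
    eegreg <- eeg_regressor(amp, st, run_cfg$tr_s, onset_regressors = onset_X)
    design <- build_design(onset_X, eegreg, run_cfg$tr_s, highpass_s)
    fit <- fit_first_level(bold$volumes, design)
    contrast <- fit$beta
  }
  list(contrast = contrast, selection = sel, flags = flags,
       truth = eeg$truth, amplitudes = amp)
}

#' Run the full synthetic pipeline
#'
#' Simulates a cohort and runs every stage through the group-level cluster
#' table: per subject and run ICA, artifact flagging, reliability-based IC
#' selection, amplitude extraction, regressor construction and first-level
#' GLM; run contrasts are averaged per subject, subjects without any
#' selected range for the target window are excluded (and reported), and
#' the remaining subject images enter a one-sample group t-map thresholded
#' at the configured voxel p and cluster extent.
#'
#' @param config A [pipeline_config].
#' @param window_tag Analysis window driving the EEG regressor.
#' @param out_dir Optional directory for the JSON report and cluster TSV.
#' @return A list of class `pipeline_report`: `subject_images`,
#'   `excluded_subjects`, `selections`, `group` (stat_map), `clusters`,
#'   `manifest`.
#' @export
run_pipeline <- function(config, window_tag = "early", out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  subject_images <- list()
  selections <- list()
  excluded <- integer(0)
  for (s in seq_len(config$n_subjects)) {
    run_imgs <- list()
    for (r in seq_len(config$n_runs)) {
      run_cfg <- config$sim
      run_cfg$seed <- derive_seed(config$seed, 1000L * s + r)
      res <- analyze_run(run_cfg, config$z_threshold, config$highpass_s,
                         config$ica_max_iter, window_tag)
      selections[[sprintf("sub%02d_run%d", s, r)]] <- res$selection$selection
      if (!is.null(res$contrast)) run_imgs[[length(run_imgs) + 1L]] <- res$contrast
    }
    if (length(run_imgs)) {
      subject_images[[sprintf("sub%02d", s)]] <- average_runs(run_imgs)
    } else {
      excluded <- c(excluded, s)
      message(sprintf("subject %d excluded: no selected range for window '%s'",
                      s, window_tag))
    }
  }
  group <- if (length(subject_images) >= 3L)
    group_stats(unname(subject_images), mode = "one_sample") else NULL
  clusters <- if (!is.null(group))
    cluster_threshold(group, p_voxel = config$glm_p, k = config$glm_k) else NULL
  manifest <- list(seed = config$seed, n_subjects = config$n_subjects,
                   n_runs = config$n_runs, window = window_tag,
                   z_threshold = config$z_threshold,
                   excluded_subjects = excluded,
                   package_version = as.character(utils::packageVersion("stefi")))
  report <- structure(list(subject_images = subject_images,
                           excluded_subjects = excluded,
                           selections = selections, group = group,
                           clusters = clusters, manifest = manifest),
                      class = "pipeline_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(list(
      manifest = manifest,
      n_selected_ranges = vapply(selections, nrow, integer(1)),
      clusters = if (!is.null(clusters)) clusters$clusters else NULL),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
    if (!is.null(clusters))
      utils::write.table(clusters$clusters, file.path(out_dir, "clusters.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d/%d subjects analyzed (window '%s')\n",
              length(x$subject_images),
              x$manifest$n_subjects, x$manifest$window))
  if (length(x$excluded_subjects))
    cat("  excluded subjects:", paste(x$excluded_subjects, collapse = ", "), "\n")
  if (!is.null(x$clusters))
    cat(sprintf("  group clusters (p < %g, k >= %d): %d\n",
                x$clusters$p_voxel, x$clusters$k, nrow(x$clusters$clusters)))
  invisible(x)
}
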