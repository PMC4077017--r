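#' Simulation configuration
#'
#' Bundles every knob of the synthetic simultaneous-EEG/fMRI generator. The
#' defaults reproduce the Go/Nogo paradigm the pipeline targets: 300 stimuli
#' per run at a 1 s stimulus-onset asynchrony (500 ms letter + 500 ms blank),
#' a 29% Nogo rate under the constraint that every Nogo is followed by at
#' least one Go, a median correct-Go response time of 0.4 s, and BOLD
#' acquisition with TR = 2.25 s and 157 volumes per run.
#'
#' Signal structure: an inhibition source emitting a smooth bump inside
#' `inhibition_window` on every stimulus — at full (log-normal) amplitude on
#' Nogo trials and at a fraction `go_leak` of it on Go trials — and a visual
#' source emitting inside `visual_window` on every stimulus. Artifact sources
#' (ballistocardiogram with a matching ECG channel, blinks with a matching
#' EOG channel, and an optional gradient artifact locked to scan triggers)
#' can be toggled individually.
#'
#' @param n_trials Stimuli per run.
#' @param p_nogo Marginal Nogo probability (must be <= 0.5; the
#'   Nogo-followed-by-Go constraint caps the feasible rate).
#' @param soa_s Stimulus onset asynchrony in seconds.
#' @param rt_median_s,rt_sdlog Median and log-scale spread of the log-normal
#'   correct-Go response-time law.
#' @param p_commission,p_omission Error rates on Nogo and Go trials.
#' @param n_channels Total EEG channels (scalp + 1 EOG + 1 ECG).
#' @param sfreq EEG working sampling rate, Hz.
#' @param tr_s,n_volumes fMRI repetition time (s) and volumes per run.
#' @param inhibition_window,visual_window Latency intervals (s post-stimulus)
#'   of the planted sources.
#' @param amp_meanlog,amp_sdlog Log-normal law of per-trial source amplitudes.
#' @param go_leak Fraction of the inhibition amplitude leaked into Go trials.
#' @param source_scale Microvolt scale of neural sources (unit-norm
#'   topographies times this gain).
#' @param noise_sd Channel white-noise standard deviation, microvolts.
#' @param bcg,blink,gradient Logical switches for the artifact sources.
#' @param grid_dim Voxel grid of the synthetic BOLD volume.
#' @param n_active_voxels Size of the contiguous coupled region.
#' @param coupling_beta BOLD gain per unit of (median-centered) trial
#'   amplitude in active voxels.
#' @param go_effect,nogo_effect,err_effect Condition onset-response heights
#'   in active voxels.
#' @param bold_noise_sd,ar_rho Standard deviation and lag-1 autocorrelation
#'   of the additive AR(1) BOLD noise.
#' @param bold_baseline Baseline BOLD intensity.
#' @param seed Master seed (mandatory; every generator output is a pure
#'   function of config + seed).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_trials = 300L, p_nogo = 0.29, soa_s = 1.0,
                       rt_median_s = 0.4, rt_sdlog = 0.25,
                       p_commission = 0.15, p_omission = 0.02,
                       n_channels = 64L, sfreq = 100,
                       tr_s = 2.25, n_volumes = 157L,
                       inhibition_window = c(0.25, 0.35),
                       visual_window = c(0.09, 0.14),
                       amp_meanlog = 0, amp_sdlog = 0.6,
                       go_leak = 0.2, source_scale = 30, noise_sd = 0.5,
                       bcg = TRUE, blink = TRUE, gradient = FALSE,
                       grid_dim = c(10L, 10L, 10L), n_active_voxels = 30L,
                       coupling_beta = 1, go_effect = 0.5, nogo_effect = 0.8,
                       err_effect = 0.5, bold_noise_sd = 1, ar_rho = 0.3,
                       bold_baseline = 100, seed) {
  if (missing(seed)) stopf("sim_config requires an explicit `seed`")
  if (!is_scalar_num(p_nogo) || p_nogo < 0 || p_nogo > 0.5)
    stopf("p_nogo must lie in [0, 0.5]: the Nogo-followed-by-Go constraint makes higher rates infeasible")
  if (n_channels < 4L) stopf("need at least 4 channels (2 scalp + EOG + ECG)")
  if (any(inhibition_window < -0.2) || any(inhibition_window > 1))
    stopf("inhibition_window must lie inside the epoch span [-0.2, 1) s")
  cfg <- as.list(environment())
  cfg$n_trials <- as.integer(n_trials)
  cfg$n_channels <- as.integer(n_channels)
  cfg$n_volumes <- as.integer(n_volumes)
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sim_config"
  cfg
}

# A compact 10-20 montage; task-relevant sites first so small simulated caps
# still carry Cz (ERP extraction) and TP9/TP10 (re-referencing).
montage_labels <- function(n_scalp) {
  base <- c("Cz", "TP9", "TP10", "Fz", "Pz", "Oz", "FCz", "CPz",
            "F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2",
            "F7", "F8", "T7", "T8", "P7", "P8", "Fp1", "Fp2",
            "FC1", "FC2", "FC5", "FC6", "CP1", "CP2", "CP5", "CP6",
            "PO3", "PO4", "PO7", "PO8", "AF3", "AF4", "AF7", "AF8",
            "F1", "F2", "F5", "F6", "C1", "C2", "C5", "C6",
            "P1", "P2", "P5", "P6", "FT7", "FT8", "TP7", "TP8",
            "PO9", "PO10", "Iz", "F9", "F10", "AFz")
  if (n_scalp <= length(base)) base[seq_len(n_scalp)]
  else c(base, paste0("X", seq_len(n_scalp - length(base))))
}

#' Generate a Go/Nogo stimulus sequence with behaviour
#'
#' Trial types follow a two-state Markov chain whose stationary Nogo fraction
#' equals `p_nogo` while never producing two consecutive Nogo trials: after a
#' Go the Nogo probability is `p_nogo / (1 - p_nogo)`, after a Nogo it is 0.
#' Correct-Go response times are log-normal; commission errors (press on
#' Nogo) and omissions (no press on Go) occur at the configured rates,
#' commissions carrying a response time.
#'
#' @param config A [sim_config].
#' @return An [event_table] with `n_trials` rows, onsets at multiples of
#'   `soa_s`.
#' @export
gen_paradigm <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_trials
  p <- config$p_nogo
  with_seed(derive_seed(config$seed, 11L), {
    p_after_go <- if (p < 0.5) p / (1 - p) else 1
    types <- character(n)
    prev_nogo <- FALSE
    u <- stats::runif(n)
    for (i in seq_len(n)) {
      types[i] <- if (!prev_nogo && u[i] < p_after_go) "Nogo" else "Go"
      prev_nogo <- types[i] == "Nogo"
    }
    rt <- rep(NA_real_, n)
    go <- types == "Go"
    press_go <- go & stats::runif(n) >= config$p_omission
    press_nogo <- !go & stats::runif(n) < config$p_commission
    pressed <- press_go | press_nogo
    rt[pressed] <- stats::rlnorm(sum(pressed),
                                 meanlog = log(config$rt_median_s),
                                 sdlog = config$rt_sdlog)
    event_table(onset = (seq_len(n) - 1) * config$soa_s,
                trial_type = types, response_time = rt, duration = 0.5)
  })
}

smooth_bump <- function(n) {
  if (n < 1L) return(numeric(0))
  0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))  # Hann, zero at both edges
}

# Random smooth unit-norm topography over channel index.
smooth_topography <- function(n_ch) {
  v <- stats::rnorm(n_ch + 8)
  v <- stats::filter(v, rep(1 / 5, 5), sides = 2)
  v <- v[!is.na(v)][seq_len(n_ch)]
  v / sqrt(sum(v^2))
}

#' Generate synthetic multichannel EEG with planted ground truth
#'
#' Builds a channels-by-samples recording as `mixing %*% sources + noise`.
#' Sources: the inhibition bump (Nogo-specific up to `go_leak`), the visual
#' bump (90-140 ms by default, every stimulus), a quasi-periodic
#' ballistocardiogram (~1.1 s inter-beat interval with jitter) echoed as QRS
#' deflections on the ECG channel, blinks echoed on the EOG channel, and an
#' optional gradient artifact: a fixed high-amplitude pattern repeated every
#' TR at scan triggers. Everything planted is returned as ground truth.
#'
#' @param events An [event_table], typically from [gen_paradigm()].
#' @param config A [sim_config].
#' @return A list with elements `recording` (a [recording]) and `truth`
#'   (topographies, per-trial amplitudes, artifact event times, the exact
#'   source matrix and mixing used).
#' @export
gen_eeg <- function(events, config) {
  validate_events(events)
  stopifnot(inherits(config, "sim_config"))
  fs <- config$sfreq
  nch <- config$n_channels
  n_scalp <- nch - 2L
  dur <- max(events$onset) + 1.5
  if (config$gradient) dur <- max(dur, config$n_volumes * config$tr_s)
  n_samp <- ceiling(dur * fs)
  onset_smp <- round(events$onset * fs)
  n_ev <- nrow(events)

  with_seed(derive_seed(config$seed, 23L), {
    labels <- c(montage_labels(n_scalp), "EOG", "ECG")
    kinds <- c(rep("scalp", n_scalp), "EOG", "ECG")

    add_bump <- function(trace, window, amps) {
      i0 <- round(window[1] * fs)
      len <- max(1L, round((window[2] - window[1]) * fs))
      bump <- smooth_bump(len)
      for (i in seq_len(n_ev)) {
        idx <- onset_smp[i] + i0 + seq_len(len)
        keep <- idx >= 1 & idx <= n_samp
        trace[idx[keep]] <- trace[idx[keep]] + amps[i] * bump[keep]
      }
      trace
    }

    # (a) inhibition source: full amplitude on Nogo, leak fraction on Go
    amp_inh <- stats::rlnorm(n_ev, config$amp_meanlog, config$amp_sdlog)
    amp_inh[events$trial_type == "Go"] <- config$go_leak *
      amp_inh[events$trial_type == "Go"]
    s_inh <- add_bump(numeric(n_samp), config$inhibition_window, amp_inh)

    # (b) visual source on every stimulus
    amp_vis <- stats::rlnorm(n_ev, config$amp_meanlog, 0.3)
    s_vis <- add_bump(numeric(n_samp), config$visual_window, amp_vis)

    # (c) ballistocardiogram: quasi-periodic wavelet + ECG-channel QRS train
    beat_times <- numeric(0)
    s_bcg <- numeric(n_samp); ecg_trace <- numeric(n_samp)
    if (config$bcg) {
      t <- 0.4
      while (t < dur - 0.6) {
        beat_times <- c(beat_times, t)
        t <- t + 1.1 + stats::rnorm(1, 0, 0.05)
      }
      wl <- round(0.5 * fs)
      tt <- seq_len(wl) / fs
      bcg_wave <- sin(2 * pi * 4 * tt) * smooth_bump(wl)       # oscillatory lobe
      qrs <- exp(-((tt - 0.05) / 0.012)^2) - 0.3 * exp(-((tt - 0.09) / 0.02)^2)
      for (bt in beat_times) {
        idx <- round(bt * fs) + seq_len(wl)
        keep <- idx <= n_samp
        s_bcg[idx[keep]] <- s_bcg[idx[keep]] + bcg_wave[keep]
        ecg_trace[idx[keep]] <- ecg_trace[idx[keep]] + 300 * qrs[keep]
      }
    }

    # (d) blinks + EOG channel deflections
    blink_times <- numeric(0)
    s_blink <- numeric(n_samp); eog_trace <- numeric(n_samp)
    if (config$blink) {
      t <- 1
      while (t < dur - 0.5) {
        t <- t + stats::rexp(1, rate = 0.15) + 0.5
        if (t < dur - 0.5) blink_times <- c(blink_times, t)
      }
      wl <- round(0.3 * fs)
      bw <- smooth_bump(wl)
      for (bt in blink_times) {
        idx <- round(bt * fs) + seq_len(wl)
        keep <- idx <= n_samp
        s_blink[idx[keep]] <- s_blink[idx[keep]] + bw[keep]
        eog_trace[idx[keep]] <- eog_trace[idx[keep]] + 100 * bw[keep]
      }
    }

    # (e) gradient artifact: fixed pattern every TR, locked to scan triggers
    s_grad <- numeric(n_samp); grad_wave <- NULL; scan_smp <- integer(0)
    if (config$gradient) {
      per <- round(config$tr_s * fs)
      grad_wave <- stats::rnorm(per, sd = 1)
      scan_smp <- seq(0L, by = per, length.out = config$n_volumes)
      for (ss in scan_smp) {
        idx <- ss + seq_len(per)
        keep <- idx <= n_samp
        s_grad[idx[keep]] <- s_grad[idx[keep]] + grad_wave[keep]
      }
    }

    src_names <- c("inhibition", "visual", "bcg", "blink", "gradient", "ecg", "eog")
    S <- rbind(s_inh, s_vis, s_bcg, s_blink, s_grad, ecg_trace, eog_trace)
    rownames(S) <- src_names

    # mixing: neural/artifact sources project onto scalp channels with smooth
    # unit-norm topographies; the ECG/EOG traces go only to their own channel
    A <- matrix(0, nch, length(src_names), dimnames = list(labels, src_names))
    scalp_rows <- seq_len(n_scalp)
    A[scalp_rows, "inhibition"] <- smooth_topography(n_scalp) * config$source_scale
    A[scalp_rows, "visual"] <- smooth_topography(n_scalp) * config$source_scale
    if (config$bcg) A[scalp_rows, "bcg"] <- smooth_topography(n_scalp) * 15
    if (config$blink) A[scalp_rows, "blink"] <- smooth_topography(n_scalp) * 20
    if (config$gradient) A[scalp_rows, "gradient"] <-
      (abs(smooth_topography(n_scalp)) + 0.5) * 300
    A[n_scalp + 1L, "eog"] <- 1
    A[n_scalp + 2L, "ecg"] <- 1
    # small leak of BCG into the auxiliary channels keeps them realistic
    if (config$bcg) A[n_scalp + 1L, "bcg"] <- 2

    dat <- A %*% S
    if (config$noise_sd > 0)
      dat <- dat + matrix(stats::rnorm(length(dat), sd = config$noise_sd),
                          nrow = nch)

    trig <- data.frame(
      sample = onset_smp,
      code = ifelse(events$trial_type == "Nogo", "S  2", "S  1"),
      stringsAsFactors = FALSE)
    if (config$gradient)
      trig <- rbind(trig, data.frame(sample = scan_smp, code = "R128"))
    trig <- trig[order(trig$sample), , drop = FALSE]
    trig <- trig[trig$sample >= 0 & trig$sample < n_samp, , drop = FALSE]

    rec <- recording(dat, sfreq = fs, channel_labels = labels,
                     channel_kinds = kinds, triggers = trig)
    truth <- list(
      mixing = A, sources = S,
      source_topographies = t(A[scalp_rows, c("inhibition", "visual"), drop = FALSE]),
      trial_amplitudes = list(inhibition = amp_inh, visual = amp_vis),
      beat_times = beat_times, blink_times = blink_times,
      gradient_waveform = grad_wave, scan_samples = scan_smp)
    list(recording = rec, truth = truth)
  })
}

#' Generate synthetic BOLD volumes coupled to trial amplitudes
#'
#' Active voxels receive HRF-convolved condition onset responses plus
#' `coupling_beta` times the median-centered per-trial inhibition amplitude;
#' inactive voxels carry baseline and noise only. Noise is AR(1) per voxel.
#' The neural signal is built on an oversampled grid and read off at volume
#' acquisition times `k * TR`.
#'
#' @param events An [event_table].
#' @param truth Ground truth from [gen_eeg()] (source of the per-trial
#'   amplitudes); may be `NULL`, in which case amplitudes are drawn afresh.
#' @param config A [sim_config].
#' @param coupling_betas Optional voxel array of coupling gains; must vanish
#'   outside the active mask.
#' @return A list with `volumes` (a [volume_series]), `active_mask` (logical
#'   3D array), `coupling_betas`, and `trial_amplitudes` (the amplitude
#'   vector actually coupled into the signal).
#' @export
gen_bold <- function(events, truth, config, coupling_betas = NULL) {
  validate_events(events)
  stopifnot(inherits(config, "sim_config"))
  dims <- config$grid_dim
  nvox <- prod(dims)
  mask <- array(FALSE, dims)
  # a compact connected region of n_active_voxels in the grid interior
  inner <- pmax(dims - 2L, 1L)
  if (prod(inner) < config$n_active_voxels)
    stopf("grid too small for %d active voxels", config$n_active_voxels)
  blk <- arrayInd(seq_len(config$n_active_voxels), .dim = inner)
  off <- ifelse(dims > 2L, 1L, 0L)
  mask[cbind(blk[, 1] + off[1], blk[, 2] + off[2], blk[, 3] + off[3])] <- TRUE
  if (is.null(coupling_betas)) {
    coupling_betas <- array(0, dims)
    coupling_betas[mask] <- config$coupling_beta
  } else {
    if (!all(dim(coupling_betas) == dims)) stopf("coupling_betas shape mismatch")
    if (any(coupling_betas[!mask] != 0))
      stopf("nonzero coupling outside the active voxel mask")
  }
  amp <- if (!is.null(truth)) truth$trial_amplitudes$inhibition else
    with_seed(derive_seed(config$seed, 37L),
              stats::rlnorm(nrow(events), config$amp_meanlog, config$amp_sdlog))
  if (length(amp) != nrow(events))
    stopf("trial amplitudes (%d) not aligned with events (%d)",
          length(amp), nrow(events))

  tr <- config$tr_s; nvol <- config$n_volumes
  dt <- tr / 16
  n_osr <- ceiling((nvol * tr + 32) / dt)
  h <- hrf_kernel(hrf_spec(), dt)
  stick <- function(onsets, weights = rep(1, length(onsets))) {
    x <- numeric(n_osr)
    idx <- pmin(n_osr, floor(onsets / dt) + 1L)
    for (i in seq_along(idx)) x[idx[i]] <- x[idx[i]] + weights[i]
    y <- stats::convolve(x, rev(h), type = "open")[seq_len(n_osr)]
    y[round((0:(nvol - 1)) * tr / dt) + 1L]
  }
  go <- events$trial_type == "Go" & events$response == "correct"
  nogo <- events$trial_type == "Nogo" & events$response == "correct"
  err <- !go & !nogo
  cond_sig <- config$go_effect * stick(events$onset[go]) +
    config$nogo_effect * stick(events$onset[nogo]) +
    (if (any(err)) config$err_effect * stick(events$onset[err]) else 0)
  coup_sig <- stick(events$onset, amp - stats::median(amp))

  with_seed(derive_seed(config$seed, 41L), {
    eps <- matrix(stats::rnorm(nvol * nvox, sd = config$bold_noise_sd), nvol, nvox)
    if (config$ar_rho != 0) {
      for (t in 2:nvol) eps[t, ] <- config$ar_rho * eps[t - 1, ] +
          sqrt(1 - config$ar_rho^2) * eps[t, ]
    }
    Y <- matrix(config$bold_baseline, nvol, nvox) + eps
    act <- which(as.vector(mask))
    if (length(act)) {
      betas <- coupling_betas[act]
      Y[, act] <- Y[, act] + outer(cond_sig, rep(1, length(act))) +
        outer(coup_sig, betas)
    }
    dat <- array(t(Y), dim = c(dims, nvol))
    list(volumes = volume_series(dat, tr_s = tr),
         active_mask = mask, coupling_betas = coupling_betas,
         trial_amplitudes = amp)
  })
}

#' Simulate a full synthetic run to disk
#'
#' Writes the events TSV, BrainVision EEG triplet, NIfTI BOLD series and a
#' ground-truth JSON for one run.
#'
#' @param config A [sim_config].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the list of written paths.
#' @export
simulate_run <- function(config, dir, prefix = "run1") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  events <- gen_paradigm(config)
  eeg <- gen_eeg(events, config)
  bold <- gen_bold(events, eeg$truth, config)
  paths <- list(
    events = file.path(dir, paste0(prefix, "_events.tsv")),
    eeg = file.path(dir, paste0(prefix, "_eeg.vhdr")),
    bold = file.path(dir, paste0(prefix, "_bold.nii.gz")),
    truth = file.path(dir, paste0(prefix, "_truth.json")))
  write_events(events, paths$events)
  write_recording(eeg$recording, paths$eeg)
  write_volumes(bold$volumes, paths$bold)
  jsonlite::write_json(list(
    trial_amplitudes = eeg$truth$trial_amplitudes,
    beat_times = eeg$truth$beat_times,
    blink_times = eeg$truth$blink_times,
    active_voxels = which(bold$active_mask),
    coupling_beta = config$coupling_beta,
    seed = config$seed), paths$truth, digits = NA, auto_unbox = TRUE)
  invisible(paths)
}
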