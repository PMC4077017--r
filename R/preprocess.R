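#' Gradient-artifact correction by sliding template subtraction
#'
#' The MR gradient artifact repeats every volume. For each channel the data
#' between consecutive scan triggers is treated as one volume epoch; from
#' each epoch the average of the surrounding `window_volumes` epochs
#' (centered window including the epoch itself, truncated at the run edges)
#' is subtracted. Samples before the first and after the last complete epoch
#' are left untouched.
#'
#' @param rec A [recording].
#' @param scan_trigger_samples 0-based sample indices of volume onsets; by
#'   default taken from triggers with code `scan_code`.
#' @param window_volumes Width of the sliding template window (volumes).
#' @param scan_code Trigger code marking volume onsets.
#' @return A corrected [recording] of identical shape and rate.
#' @export
subtract_gradient_template <- function(rec, scan_trigger_samples = NULL,
                                       window_volumes = 21L,
                                       scan_code = "R128") {
  stopifnot(inherits(rec, "recording"))
  if (is.null(scan_trigger_samples))
    scan_trigger_samples <- rec$triggers$sample[rec$triggers$code == scan_code]
  trg <- sort(as.integer(scan_trigger_samples))
  if (length(trg) < window_volumes)
    stopf("need at least window_volumes (%d) scan triggers, got %d",
          window_volumes, length(trg))
  gaps <- diff(trg)
  per <- round(stats::median(gaps))
  if (any(abs(gaps - per) > 1L))
    stopf("irregular scan trigger spacing: gaps deviate by more than 1 sample")
  n_ep <- length(trg)
  last_ok <- trg[n_ep] + per <= ncol(rec$data)
  if (!last_ok) n_ep <- n_ep - 1L
  half <- (window_volumes - 1L) %/% 2L
  dat <- rec$data
  for (ch in seq_len(nrow(dat))) {
    # epochs as columns: per x n_ep
    E <- matrix(0, per, n_ep)
    for (e in seq_len(n_ep)) E[, e] <- dat[ch, trg[e] + seq_len(per)]
    # running mean over epochs via cumulative sums along the epoch axis
    CS <- apply(E, 1, cumsum)            # n_ep x per
    CS <- rbind(0, CS)
    for (e in seq_len(n_ep)) {
      lo <- max(1L, e - half); hi <- min(n_ep, e + half)
      tmpl <- (CS[hi + 1L, ] - CS[lo, ]) / (hi - lo + 1L)
      dat[ch, trg[e] + seq_len(per)] <- E[, e] - tmpl
    }
  }
  rec$data <- dat
  rec
}

#' Bandpass filter and downsample a recording
#'
#' Zero-phase Butterworth filtering (forward-backward) removing slow drifts
#' below `low` Hz and residual scanner/high-frequency content above `high`
#' Hz, then integer-factor decimation to `out_sfreq`. The low-pass leg is
#' applied at the input rate as the anti-alias filter before decimation; the
#' high-pass leg runs at the output rate where its normalized corner is well
#' conditioned. Trigger samples are remapped to the new rate.
#'
#' @param rec A [recording].
#' @param low,high Band edges in Hz.
#' @param out_sfreq Target sampling rate; must divide `rec$sfreq`.
#' @return A filtered, downsampled [recording].
#' @export
bandpass_downsample <- function(rec, low = 0.2, high = 48, out_sfreq = 100) {
  stopifnot(inherits(rec, "recording"))
  if (out_sfreq > rec$sfreq) stopf("out_sfreq exceeds the input rate")
  if (high >= out_sfreq / 2)
    stopf("high edge (%g Hz) must be below the output Nyquist (%g Hz)",
          high, out_sfreq / 2)
  fac <- rec$sfreq / out_sfreq
  if (abs(fac - round(fac)) > 1e-9)
    stopf("out_sfreq must divide the input rate (factor %.3f)", fac)
  fac <- as.integer(round(fac))
  dat <- rec$data
  lp <- signal::butter(4, high / (rec$sfreq / 2), type = "low")
  for (ch in seq_len(nrow(dat)))
    dat[ch, ] <- signal::filtfilt(lp, dat[ch, ])
  if (fac > 1L) dat <- dat[, seq(1L, ncol(dat), by = fac), drop = FALSE]
  hp <- signal::butter(2, low / (out_sfreq / 2), type = "high")
  for (ch in seq_len(nrow(dat)))
    dat[ch, ] <- signal::filtfilt(hp, dat[ch, ])
  trig <- rec$triggers
  if (nrow(trig)) {
    trig$sample <- as.integer(round(trig$sample / fac))
    trig <- trig[trig$sample < ncol(dat), , drop = FALSE]
  }
  recording(dat, sfreq = out_sfreq, channel_labels = rec$channel_labels,
            channel_kinds = rec$channel_kinds, triggers = trig)
}

#' Detect heartbeats or blinks on an auxiliary channel
#'
#' Template-matching detection: (1) the auxiliary channel is bandpassed and
#' provisional peaks are found as refractory-separated local maxima above a
#' robust threshold; (2) the event template is the average waveform around
#' the provisional peaks; (3) final events are local maxima of the
#' normalized cross-correlation of the channel with this template exceeding
#' `theta` times its maximum, separated by the refractory period `rho`.
#'
#' @param rec A [recording].
#' @param channel_kind `"ECG"` (heartbeats) or `"EOG"` (blinks).
#' @param theta Relative cross-correlation threshold.
#' @param rho_s Refractory period in seconds (default 0.4 for ECG, 0.25 for
#'   EOG).
#' @return Numeric vector of event times in seconds.
#' @export
detect_artifact_events <- function(rec, channel_kind = c("ECG", "EOG"),
                                   theta = 0.6, rho_s = NULL) {
  channel_kind <- match.arg(channel_kind)
  stopifnot(inherits(rec, "recording"))
  idx <- which(rec$channel_kinds == channel_kind)
  if (!length(idx)) stopf("no channel of kind %s present", channel_kind)
  x <- rec$data[idx[1L], ]
  fs <- rec$sfreq
  if (is.null(rho_s)) rho_s <- if (channel_kind == "ECG") 0.4 else 0.25
  band <- if (channel_kind == "ECG") c(5, 20) else c(0.5, 8)
  bf <- signal::butter(2, pmin(band / (fs / 2), 0.99), type = "pass")
  xf <- signal::filtfilt(bf, x)
  s <- stats::sd(xf)
  if (s < .Machine$double.eps) stopf("channel is flat; no events detectable")
  thr <- 2.5 * s
  peaks <- local_maxima(xf, min_dist = round(rho_s * fs), height = thr)
  if (length(peaks) < 10L)
    stopf("only %d provisional peaks found; signal too weak for template detection",
          length(peaks))
  half <- round(0.25 * fs)
  keep <- peaks > half & peaks <= length(x) - half
  seg <- vapply(peaks[keep], function(p) x[(p - half):(p + half)],
                numeric(2L * half + 1L))
  tmpl <- rowMeans(seg); tmpl <- tmpl - mean(tmpl)
  cc <- normalized_xcorr(x, tmpl)
  final <- local_maxima(cc, min_dist = round(rho_s * fs),
                        height = theta * max(cc, na.rm = TRUE))
  sort(final - 1L) / fs  # 0-based sample convention
}

# Local maxima of `x` above `height`, greedily enforcing a minimum distance
# (the larger peak wins).
local_maxima <- function(x, min_dist, height = -Inf) {
  n <- length(x)
  cand <- which(x > height)
  cand <- cand[cand > 1L & cand < n]
  cand <- cand[x[cand] >= x[cand - 1L] & x[cand] >= x[cand + 1L]]
  if (!length(cand)) return(integer(0))
  cand <- cand[order(x[cand], decreasing = TRUE)]
  taken <- integer(0)
  for (p in cand)
    if (!length(taken) || all(abs(taken - p) >= min_dist)) taken <- c(taken, p)
  sort(taken)
}

# Normalized cross-correlation of x with a (zero-mean) template, aligned so
# cc[i] scores the window centered at sample i.
normalized_xcorr <- function(x, tmpl) {
  L <- length(tmpl)
  num <- stats::filter(x, rev(tmpl), sides = 2)
  s1 <- stats::filter(x, rep(1, L), sides = 2)
  s2 <- stats::filter(x^2, rep(1, L), sides = 2)
  denom <- sqrt(pmax(s2 - s1^2 / L, 0)) * sqrt(sum(tmpl^2))
  cc <- as.numeric(num / pmax(denom, .Machine$double.eps))
  cc[!is.finite(cc)] <- 0
  cc
}

#' Flag independent components locked to artifact events
#'
#' For each IC the event-locked average over a fixed peri-event window is
#' computed and summarized by its RMS. The same statistic is computed for
#' `n_null` surrogate event sets obtained by circularly shifting the event
#' times (seeded); an IC is flagged when its observed locked-average RMS
#' exceeds the 99th percentile of its surrogate distribution, giving a
#' nominal 1% false-flag rate per IC.
#'
#' @param dec A `decomposition` from [fit_unmixing()].
#' @param rec The [recording] the decomposition was fitted on.
#' @param event_times_s Artifact event times in seconds (>= 20 required).
#' @param n_null Number of surrogate event sets (>= 50).
#' @param seed RNG seed for the surrogate shifts.
#' @param reason Label stored with the flags (`"bcg"` or `"blink"`).
#' @param window_s Peri-event window, seconds.
#' @param prob Surrogate percentile used as flagging threshold.
#' @return Integer vector of flagged IC indices with a `reason` attribute;
#'   flags are also merged into the returned decomposition when assigned.
#' @export
flag_artifact_ics <- function(dec, rec, event_times_s, n_null = 200L, seed,
                              reason = "bcg", window_s = c(-0.2, 0.5),
                              prob = 0.99) {
  stopifnot(inherits(dec, "decomposition"), inherits(rec, "recording"))
  if (length(event_times_s) < 20L)
    stopf("need >= 20 artifact events, got %d", length(event_times_s))
  if (n_null < 50L) stopf("n_null must be >= 50 for a usable null")
  fs <- rec$sfreq
  act <- ic_activations(dec, rec)
  n <- ncol(act)
  off <- round(window_s[1] * fs):(round(window_s[2] * fs) - 1L)
  ev <- round(event_times_s * fs)
  ev <- ev[ev + min(off) >= 0L & ev + max(off) < n]
  locked_rms <- function(ev_smp) {
    # circular indexing so surrogate (shifted) event sets stay in range
    idx <- (outer(ev_smp, off, "+") %% n) + 1L  # events x window, 1-based
    m <- matrix(0, nrow(act), length(off))
    for (j in seq_along(off))
      m[, j] <- rowMeans(act[, idx[, j], drop = FALSE])
    sqrt(rowMeans(m^2))
  }
  obs <- locked_rms(ev)
  null <- with_seed(seed, {
    shifts <- sample.int(n - 2L, n_null, replace = TRUE)
    vapply(shifts, function(s) locked_rms((ev + s) %% n), numeric(nrow(act)))
  })
  thr <- apply(null, 1, stats::quantile, probs = prob, names = FALSE)
  flags <- which(obs > thr)
  attr(flags, "reason") <- rep(reason, length(flags))
  attr(flags, "rms") <- obs
  flags
}

#' Remove flagged ICs from channel-space data
#'
#' Back-projects the decomposition excluding the given ICs, yielding
#' artifact-corrected channel-space EEG (used by the fixed-window ERP path;
#' the IC path works on IC time courses directly, simply skipping flagged
#' ICs).
#'
#' @param rec A [recording].
#' @param dec A `decomposition`.
#' @param exclude Integer IC indices to remove (defaults to the stored
#'   artifact flags).
#' @return A cleaned [recording].
#' @export
remove_ics <- function(rec, dec, exclude = dec$artifact_flags) {
  act <- ic_activations(dec, rec)
  if (length(exclude)) act[exclude, ] <- 0
  dat <- dec$mixing %*% act + dec$center
  rownames(dat) <- rec$channel_labels
  rec$data <- dat
  rec
}
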