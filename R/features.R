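#' Median correct-Go response time
#'
#' @param events An [event_table].
#' @return Median RT of correct Go trials, seconds (even counts: mean of the
#'   central pair).
#' @export
median_rt <- function(events) {
  validate_events(events)
  rts <- events$response_time[events$trial_type == "Go" &
                                events$response == "correct"]
  rts <- rts[!is.na(rts)]
  if (!length(rts)) stopf("no correct Go trials with a response time")
  stats::median(rts)
}

#' Polarity-corrected single-trial amplitudes of selected ICs
#'
#' For every trial and every selected (IC, latency range) pair, the mean IC
#' amplitude over the half-open range is taken, multiplied by the range's
#' polarity (so reliable Nogo activity is positive-going), and summed over
#' all ranges selected for the window — one value per trial, covering ALL
#' trials (Go, Nogo and errors), since the regressor must span the whole
#' run.
#'
#' @param ep An [epoch_set] of IC activations.
#' @param selection A `latency_ranges` table with a `window` column (from
#'   [select_for_windows()] or `select_ics()$selection`).
#' @param window_tag Window to extract (`"early"`, `"late"`, `"visual"`).
#' @return An object of class `amplitude_vector`: `values`, `onsets_s`,
#'   `trial_type`, `label`.
#' @export
single_trial_amplitudes <- function(ep, selection, window_tag) {
  stopifnot(inherits(ep, "epoch_set"))
  sel <- selection[selection$window == window_tag, , drop = FALSE]
  if (!nrow(sel))
    stopf("no latency range selected for window '%s'; subject excluded for this window",
          window_tag)
  tol <- 1e-9
  vals <- numeric(dim(ep$values)[1])
  for (k in seq_len(nrow(sel))) {
    idx <- which(ep$times >= sel$t_on[k] - tol & ep$times < sel$t_off[k] - tol)
    if (!length(idx)) stopf("latency range [%g, %g) outside the epoch span",
                            sel$t_on[k], sel$t_off[k])
    seg <- ep$values[, sel$ic[k], idx, drop = FALSE]
    vals <- vals + sel$polarity[k] * apply(seg, 1, mean)
  }
  structure(list(values = vals, onsets_s = ep$events$onset,
                 trial_type = ep$events$trial_type, label = window_tag),
            class = "amplitude_vector")
}

#' @export
print.amplitude_vector <- function(x, ...) {
  cat(sprintf("<amplitude_vector> '%s': %d trials, mean %.3g, IQR %.3g\n",
              x$label, length(x$values), mean(x$values), stats::IQR(x$values)))
  invisible(x)
}

#' Re-reference scalp channels to linked mastoid-adjacent electrodes
#'
#' Subtracts the mean of the two reference channels (TP9/TP10 by default)
#' from every scalp channel. Idempotent: after one pass the reference mean
#' is zero. Non-scalp channels (EOG/ECG) are left untouched.
#'
#' @param rec A [recording].
#' @param refs Labels of the two reference channels.
#' @return A re-referenced [recording].
#' @export
rereference <- function(rec, refs = c("TP9", "TP10")) {
  stopifnot(inherits(rec, "recording"))
  ri <- match(refs, rec$channel_labels)
  if (anyNA(ri))
    stopf("reference channel(s) missing: %s",
          paste(refs[is.na(ri)], collapse = ", "))
  refmean <- colMeans(rec$data[ri, , drop = FALSE])
  scalp <- rec$channel_kinds == "scalp"
  rec$data[scalp, ] <- sweep(rec$data[scalp, , drop = FALSE], 2, refmean)
  rec
}

#' Fixed-window ERP single-trial amplitudes
#'
#' The classical comparison path: per-trial mean amplitude at one electrode
#' over a fixed latency window (N2: 280-340 ms, P3: 350-570 ms
#' post-stimulus), computed on artifact-corrected, re-referenced
#' channel-space epochs. No polarity inversion is applied; the values keep
#' their raw sign.
#'
#' @param ep An [epoch_set] of channel data.
#' @param electrode Channel label (default `"Cz"`).
#' @param window Half-open latency window in seconds.
#' @param label Label stored on the output.
#' @return An `amplitude_vector`.
#' @export
erp_amplitudes <- function(ep, electrode = "Cz", window = c(0.280, 0.340),
                           label = "N2") {
  stopifnot(inherits(ep, "epoch_set"))
  u <- match(electrode, ep$unit_labels)
  if (is.na(u)) stopf("electrode %s not present", electrode)
  tol <- 1e-9
  idx <- which(ep$times >= window[1] - tol & ep$times < window[2] - tol)
  if (!length(idx)) stopf("window [%g, %g) outside the epoch span",
                          window[1], window[2])
  vals <- apply(ep$values[, u, idx, drop = FALSE], 1, mean)
  structure(list(values = vals, onsets_s = ep$events$onset,
                 trial_type = ep$events$trial_type, label = label),
            class = "amplitude_vector")
}
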