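#' Canonical double-gamma HRF specification
#'
#' The canonical hemodynamic response: a gamma density peaking around 5-6 s
#' minus a later undershoot gamma at one sixth of its height, truncated at
#' `length_s`. The kernel is zero at lag 0 and is normalized to unit peak.
#'
#' @param peak_delay_s Delay (shape, with unit dispersion) of the main lobe.
#' @param undershoot_delay_s Delay of the undershoot lobe.
#' @param ratio Main-lobe-to-undershoot amplitude ratio.
#' @param length_s Kernel support in seconds.
#' @return A list of class `hrf_spec`.
#' @export
hrf_spec <- function(peak_delay_s = 6, undershoot_delay_s = 16, ratio = 6,
                     length_s = 32) {
  structure(list(peak_delay_s = peak_delay_s,
                 undershoot_delay_s = undershoot_delay_s,
                 ratio = ratio, length_s = length_s), class = "hrf_spec")
}

#' Sample an HRF kernel on a time grid
#'
#' @param spec An [hrf_spec].
#' @param dt Sampling step in seconds.
#' @return Numeric vector `h(0), h(dt), ...` up to `length_s`.
#' @export
hrf_kernel <- function(spec = hrf_spec(), dt) {
  t <- seq(0, spec$length_s, by = dt)
  h <- stats::dgamma(t, shape = spec$peak_delay_s, rate = 1) -
    stats::dgamma(t, shape = spec$undershoot_delay_s, rate = 1) / spec$ratio
  h / max(h)
}

#' Resample a trial-amplitude vector at scan times
#'
#' Fits a cubic smoothing spline to the (onset, amplitude) pairs and
#' evaluates it at the volume acquisition times, bridging the EEG-derived
#' sampling rate (one value per trial, 1 Hz at the default paradigm) and the
#' fMRI acquisition rate (1/TR). The default smoothing is near-zero (the
#' interpolating limit): the spline's job here is resampling, and heavier
#' smoothing would erase the trial-to-trial amplitude variability that the
#' regressor exists to carry. `lambda = NULL` requests generalized
#' cross-validation instead. Evaluation outside the covered onset span is
#' clamped to the boundary values.
#'
#' @param amp An `amplitude_vector` (see [single_trial_amplitudes()]) or a
#'   list with `onsets_s` and `values`.
#' @param scan_times_s Numeric vector of volume acquisition times (s).
#' @param lambda Non-negative smoothing parameter passed to
#'   [stats::smooth.spline()] (values at or near 0 give the interpolating
#'   limit), or `NULL` for generalized cross-validation.
#' @return Numeric vector, one value per scan time.
#' @export
resample_to_scans <- function(amp, scan_times_s, lambda = 1e-8) {
  x <- amp$onsets_s; y <- amp$values
  if (length(x) < 4L) stopf("need at least 4 trials to fit the smoothing spline")
  fit <- if (is.null(lambda))
    stats::smooth.spline(x, y, cv = FALSE)
  else
    stats::smooth.spline(x, y, lambda = max(lambda, 1e-15), all.knots = TRUE)
  tt <- pmin(pmax(scan_times_s, min(x)), max(x))
  stats::predict(fit, tt)$y
}

#' Normalize a regressor to unit inter-quartile range
#'
#' Subtracts the median and divides by the inter-quartile range (linear
#' interpolation quartiles), so the output has median 0 and IQR exactly 1.
#'
#' @param values Numeric vector.
#' @return Normalized vector.
#' @export
normalize_iqr <- function(values) {
  iqr <- stats::IQR(values, type = 7)
  if (iqr <= 0) stopf("IQR is zero; cannot normalize a constant regressor")
  (values - stats::median(values)) / iqr
}

#' Convolve scan-grid values with the canonical HRF
#'
#' The kernel is sampled at `tr_s / oversample` and decimated back onto the
#' scan grid; the causal discrete convolution is truncated to the input
#' length.
#'
#' @param values Numeric vector on the scan grid.
#' @param tr_s Repetition time (s).
#' @param hrf An [hrf_spec].
#' @param oversample Oversampling factor for kernel sampling.
#' @return Numeric vector, same length as `values`.
#' @export
hrf_convolve <- function(values, tr_s, hrf = hrf_spec(), oversample = 16L) {
  h_fine <- hrf_kernel(hrf, tr_s / oversample)
  h <- h_fine[seq(1L, length(h_fine), by = oversample)]
  n <- length(values)
  out <- stats::convolve(values, rev(h), type = "open")[seq_len(n)]
  out
}

#' Build condition onset regressors
#'
#' Zero-duration delta trains at correct-Go, correct-Nogo and error
#' (omission + commission) onsets, convolved with the canonical HRF on an
#' oversampled grid and read off at volume acquisition times. Conditions
#' with no events are dropped with a warning.
#'
#' @param events An [event_table].
#' @param n_vols Number of analyzed volumes.
#' @param tr_s Repetition time (s).
#' @param hrf An [hrf_spec].
#' @param oversample Oversampling factor of the convolution grid.
#' @return Matrix `n_vols x (<=3)` with columns among `go`, `nogo`, `errors`.
#' @export
build_onset_regressors <- function(events, n_vols, tr_s, hrf = hrf_spec(),
                                   oversample = 16L) {
  validate_events(events)
  dt <- tr_s / oversample
  n_osr <- ceiling((n_vols * tr_s + hrf$length_s) / dt)
  h <- hrf_kernel(hrf, dt)
  scan_idx <- round((0:(n_vols - 1)) * tr_s / dt) + 1L
  one <- function(onsets) {
    x <- numeric(n_osr)
    idx <- floor(onsets / dt) + 1L
    for (i in idx) if (i >= 1 && i <= n_osr) x[i] <- x[i] + 1
    stats::convolve(x, rev(h), type = "open")[seq_len(n_osr)][scan_idx]
  }
  sets <- list(
    go = events$onset[events$trial_type == "Go" & events$response == "correct"],
    nogo = events$onset[events$trial_type == "Nogo" & events$response == "correct"],
    errors = events$onset[events$response %in% c("omission", "commission")])
  keep <- vapply(sets, function(o) length(o) > 0L, logical(1))
  if (any(!keep))
    warning(sprintf("condition(s) with zero events dropped: %s",
                    paste(names(sets)[!keep], collapse = ", ")), call. = FALSE)
  out <- vapply(sets[keep], one, numeric(n_vols))
  out
}

#' Orthogonalize a regressor against nuisance columns
#'
#' Returns the residual of the least-squares projection of `r` onto the span
#' of the nuisance columns plus an intercept, so the output is uncorrelated
#' with each nuisance regressor. Rank-deficient nuisance sets are handled by
#' the pseudo-inverse (with a message).
#'
#' @param r Numeric vector.
#' @param nuisance Matrix (columns are nuisance regressors) or `NULL`.
#' @return Numeric vector, same length as `r`.
#' @export
orthogonalize <- function(r, nuisance = NULL) {
  X <- cbind(intercept = rep(1, length(r)), nuisance)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    message("orthogonalize: rank-deficient nuisance set; using pseudo-inverse")
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-10
    fit <- sv$u[, pos, drop = FALSE] %*%
      crossprod(sv$u[, pos, drop = FALSE], r)
    return(as.numeric(r - fit))
  }
  as.numeric(qr.resid(qrX, r))
}

#' Build an EEG-derived fMRI regressor
#'
#' The fixed pipeline: smoothing-spline resampling at scan times,
#' normalization to unit inter-quartile range, convolution with the
#' canonical HRF, and (optionally) orthogonalization against the onset
#' regressors.
#'
#' @inheritParams resample_to_scans
#' @inheritParams hrf_convolve
#' @param onset_regressors Matrix of nuisance onset regressors, or `NULL` to
#'   skip orthogonalization (the visual regressor path).
#' @return Numeric vector, one value per scan time.
#' @export
eeg_regressor <- function(amp, scan_times_s, tr_s, hrf = hrf_spec(),
                          onset_regressors = NULL, lambda = 1e-8) {
  v <- resample_to_scans(amp, scan_times_s, lambda = lambda)
  v <- normalize_iqr(v)
  v <- hrf_convolve(v, tr_s, hrf)
  if (!is.null(onset_regressors)) v <- orthogonalize(v, onset_regressors)
  v
}
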