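#' Segment unit time courses into baseline-corrected epochs
#'
#' Cuts epochs of `window` seconds (default -0.2 to +1.0 s, i.e. 1200 ms
#' starting 200 ms before stimulus onset) around every event onset, at the
#' working rate of the input. The mean over the baseline interval (default
#' the 200 ms pre-stimulus span) is subtracted per trial and unit. Trials
#' whose epoch would cross the run edge are dropped with a message. Trials
#' are labelled `correct_go`, `correct_nogo`, `omission` or `commission`.
#'
#' @param timecourses Units-by-samples matrix (IC activations or channels) or
#'   a [recording].
#' @param events An [event_table].
#' @param sfreq Sampling rate in Hz (taken from the recording when given).
#' @param window Epoch span in seconds relative to stimulus onset, half-open.
#' @param baseline Baseline interval in seconds, half-open.
#' @return An object of class `epoch_set`: `values` (trials x units x time),
#'   `times` (epoch time axis, s), `sfreq`, `condition` (per-trial label),
#'   `trial_index` (row of `events` each epoch comes from), `events`.
#' @export
epoch_units <- function(timecourses, events, sfreq = NULL,
                        window = c(-0.2, 1.0), baseline = c(-0.2, 0)) {
  if (inherits(timecourses, "recording")) {
    sfreq <- timecourses$sfreq
    tc <- timecourses$data
  } else tc <- as.matrix(timecourses)
  if (is.null(sfreq)) stopf("sfreq required when timecourses is a matrix")
  validate_events(events)
  n_time <- round((window[2] - window[1]) * sfreq)
  off <- round(window[1] * sfreq) + 0:(n_time - 1L)   # 0-based sample offsets
  onset_smp <- round(events$onset * sfreq)
  ok <- onset_smp + off[1] >= 0L & onset_smp + off[n_time] < ncol(tc)
  if (any(!ok))
    message(sprintf("epoch_units: dropped %d trial(s) too close to the run edge",
                    sum(!ok)))
  keep <- which(ok)
  n_tr <- length(keep); n_u <- nrow(tc)
  vals <- array(0, dim = c(n_tr, n_u, n_time))
  for (i in seq_len(n_tr)) {
    idx <- onset_smp[keep[i]] + off + 1L
    vals[i, , ] <- tc[, idx]
  }
  times <- window[1] + (0:(n_time - 1L)) / sfreq
  bidx <- which(times >= baseline[1] & times < baseline[2])
  if (length(bidx)) {
    bl <- apply(vals[, , bidx, drop = FALSE], c(1, 2), mean)
    vals <- vals - array(rep(bl, n_time), dim = dim(vals))
  }
  cond <- ifelse(events$response[keep] == "correct",
                 ifelse(events$trial_type[keep] == "Go", "correct_go", "correct_nogo"),
                 events$response[keep])
  structure(list(values = vals, times = times, sfreq = sfreq,
                 condition = cond, trial_index = keep,
                 events = events[keep, , drop = FALSE],
                 unit_labels = rownames(tc) %||% paste0("U", seq_len(n_u))),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<epoch_set> %d trials x %d units x %d samples @ %g Hz, t in [%g, %g) s\n",
              d[1], d[2], d[3], x$sfreq, x$times[1],
              x$times[length(x$times)] + 1 / x$sfreq))
  print(table(x$condition))
  invisible(x)
}

#' Pointwise mean and variance of one condition
#'
#' @param ep An [epoch_set].
#' @param condition One of the condition labels, or a logical/integer trial
#'   selector; `"pooled"` pools correct Go and correct Nogo trials (the
#'   visual-IC path).
#' @return A list of class `condition_stats` with `mean` and unbiased `var`
#'   (units x time) and the epoch count `n`.
#' @export
condition_stats <- function(ep, condition) {
  stopifnot(inherits(ep, "epoch_set"))
  sel <- if (is.character(condition) && length(condition) == 1L) {
    if (condition == "pooled") ep$condition %in% c("correct_go", "correct_nogo")
    else ep$condition == condition
  } else condition
  v <- ep$values[sel, , , drop = FALSE]
  n <- dim(v)[1]
  if (n < 2L) stopf("need >= 2 epochs in condition '%s', got %d",
                    paste(condition, collapse = ","), n)
  m <- apply(v, c(2, 3), mean)
  s2 <- apply(v, c(2, 3), stats::var)
  structure(list(mean = m, var = s2, n = n,
                 condition = if (is.character(condition)) condition else "custom",
                 times = ep$times),
            class = "condition_stats")
}

#' Pointwise reliability statistic (t standardized to Z)
#'
#' Computes pointwise t-values per unit and time point — two-sample
#' (unpooled/Welch form) between conditions `a` and `b`, or one-sample of
#' `a` against the (baseline-corrected) zero level — and standardizes them
#' to per-trial Z scores by `Z = t / sqrt(n_ref)`, where `n_ref` is the
#' epoch count of the smaller condition. The degrees of freedom are recorded
#' conservatively as `n_ref - 1`. With 90 Nogo epochs this makes the
#' selection threshold |Z| > 0.275 correspond to a two-sided p of 0.01
#' (t = 0.275 * sqrt(90) ~ 2.61 at df = 89).
#'
#' Points with zero variance yield Z = 0 when the mean difference is also
#' zero and +/-Inf (flagged via the `infinite` attribute) otherwise.
#'
#' @param a,b [condition_stats()] objects; `b = NULL` selects the one-sample
#'   mode.
#' @return An object of class `z_series`: `z` (units x time), `t`, `mode`,
#'   `n_ref`, `df`, `times`.
#' @export
pointwise_z <- function(a, b = NULL) {
  stopifnot(inherits(a, "condition_stats"))
  if (is.null(b)) {
    se2 <- a$var / a$n
    tval <- ifelse(se2 > 0, a$mean / sqrt(se2),
                   ifelse(a$mean == 0, 0, sign(a$mean) * Inf))
    n_ref <- a$n
    mode <- "one_sample"
  } else {
    stopifnot(inherits(b, "condition_stats"))
    se2 <- a$var / a$n + b$var / b$n
    d <- a$mean - b$mean
    tval <- ifelse(se2 > 0, d / sqrt(se2), ifelse(d == 0, 0, sign(d) * Inf))
    n_ref <- min(a$n, b$n)
    mode <- "two_sample"
  }
  z <- tval / sqrt(n_ref)
  structure(list(z = z, t = tval, mode = mode, n_ref = n_ref,
                 df = n_ref - 1L, times = a$times,
                 infinite = any(is.infinite(z))),
            class = "z_series")
}

#' Extract above-threshold latency ranges with polarity
#'
#' Scans each unit's |Z| series for maximal contiguous runs exceeding the
#' threshold. A range starts at the first above-threshold sample time and
#' ends at the first below-threshold sample time after the run (half-open).
#' In `mode = "nogo"` the condition averages over the range decide
#' dominance: the condition with the larger absolute mean is noted, the
#' polarity is the sign of that dominant average, and ranges dominated by Go
#' are discarded (keeping only ranges with larger absolute Nogo amplitude).
#' In `mode = "visual"` the polarity is the sign of the pooled average over
#' the range and no dominance filter applies.
#'
#' @param z A [pointwise_z()] result.
#' @param stats_nogo,stats_go Condition statistics used for the dominance and
#'   polarity rules (`stats_nogo` doubles as the pooled stats in visual
#'   mode).
#' @param threshold Z threshold (default 0.275).
#' @param mode `"nogo"` or `"visual"`.
#' @return A data frame of class `latency_ranges` with columns `ic`, `t_on`,
#'   `t_off`, `polarity`, `dominant_condition`, `peak_absz`.
#' @export
extract_ranges <- function(z, stats_nogo = NULL, stats_go = NULL,
                           threshold = 0.275, mode = c("nogo", "visual")) {
  mode <- match.arg(mode)
  stopifnot(inherits(z, "z_series"))
  if (mode == "nogo" && (is.null(stats_nogo) || is.null(stats_go)))
    stopf("nogo mode needs both condition statistics for the dominance rule")
  if (mode == "visual" && is.null(stats_nogo))
    stopf("visual mode needs the pooled condition statistics for polarity")
  dt <- diff(z$times[1:2])
  rows <- list()
  for (u in seq_len(nrow(z$z))) {
    above <- abs(z$z[u, ]) > threshold
    above[is.na(above)] <- FALSE
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      i0 <- starts[k]; i1 <- ends[k]
      t_on <- z$times[i0]
      t_off <- z$times[i1] + dt
      idx <- i0:i1
      if (mode == "nogo") {
        m_n <- mean(stats_nogo$mean[u, idx])
        m_g <- mean(stats_go$mean[u, idx])
        if (abs(m_g) > abs(m_n)) next  # Go-dominated: discard
        dom <- "Nogo"
        pol <- if (m_n >= 0) 1 else -1
      } else {
        dom <- "n/a"
        mp <- mean(stats_nogo$mean[u, idx])
        pol <- if (mp >= 0) 1 else -1
      }
      rows[[length(rows) + 1L]] <- data.frame(
        ic = u, t_on = t_on, t_off = t_off, polarity = pol,
        dominant_condition = dom, peak_absz = max(abs(z$z[u, idx])),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(ic = integer(0), t_on = numeric(0), t_off = numeric(0),
               polarity = numeric(0), dominant_condition = character(0),
               peak_absz = numeric(0), stringsAsFactors = FALSE)
  class(res) <- c("latency_ranges", "data.frame")
  res
}

#' Participant-specific analysis windows
#'
#' The early window spans 200 ms post-stimulus to the participant's median
#' correct-Go response time; the late window spans median RT - 100 ms to
#' median RT + 300 ms (the two may overlap); the visual window is fixed at
#' 90-140 ms.
#'
#' @param median_rt_s Median correct-Go RT in seconds.
#' @return Named list of `c(start, end)` windows (class `analysis_windows`).
#' @export
analysis_windows <- function(median_rt_s) {
  if (!is_scalar_num(median_rt_s) || median_rt_s <= 0.2)
    stopf("median RT must exceed 0.2 s for a non-empty early window")
  structure(list(early = c(0.2, median_rt_s),
                 late = c(median_rt_s - 0.1, median_rt_s + 0.3),
                 visual = c(0.09, 0.14)),
            class = "analysis_windows")
}

#' Tag latency ranges by strict window containment
#'
#' A range is tagged with a window if and only if it rises above threshold
#' at or after the window start and falls below threshold at or before the
#' window end (`start <= t_on` and `t_off <= end`). A range inside the
#' early/late overlap is tagged with both; ranges contained in no window are
#' dropped.
#'
#' @param ranges A [extract_ranges()] result.
#' @param windows An [analysis_windows()] list (or any named list of
#'   `c(start, end)`).
#' @param which_windows Window names to test against.
#' @return A `latency_ranges` data frame with an added `window` column, one
#'   row per (range, containing window).
#' @export
select_for_windows <- function(ranges, windows,
                               which_windows = setdiff(names(windows), "visual")) {
  tol <- 1e-9
  rows <- list()
  for (w in which_windows) {
    win <- windows[[w]]
    hit <- ranges$t_on >= win[1] - tol & ranges$t_off <= win[2] + tol
    if (any(hit)) {
      r <- ranges[hit, , drop = FALSE]
      r$window <- w
      rows[[w]] <- r
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else cbind(
    ranges[integer(0), , drop = FALSE],
    data.frame(window = character(0), stringsAsFactors = FALSE))
  rownames(res) <- NULL
  class(res) <- c("latency_ranges", "data.frame")
  res
}

#' Data-driven selection of task-related independent components
#'
#' The full classification-and-selection procedure for one run: condition
#' statistics on the IC epochs, the pointwise reliability statistic
#' (two-sample Nogo vs Go in `mode = "nogo"`, one-sample pooled against
#' baseline in `mode = "visual"`), extraction of above-threshold latency
#' ranges with polarity and Nogo-dominance filtering, and strict containment
#' tagging against the participant's analysis windows (anchored on the
#' median correct-Go RT in nogo mode, the fixed 90-140 ms window in visual
#' mode). ICs listed in `exclude` (artifact ICs) never enter the candidate
#' set.
#'
#' @param ep An [epoch_set] of IC activations.
#' @param mode `"nogo"` or `"visual"`.
#' @param z_threshold Reliability threshold on |Z|.
#' @param exclude Integer IC indices to exclude (artifact ICs).
#' @param median_rt_s Median correct-Go RT; computed from the epochs' events
#'   when `NULL`.
#' @return An object of class `ic_selection`: the tagged `selection` table,
#'   the `z` series, condition statistics, the windows used and bookkeeping.
#' @export
select_ics <- function(ep, mode = c("nogo", "visual"), z_threshold = 0.275,
                       exclude = integer(0), median_rt_s = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(ep, "epoch_set"))
  if (z_threshold <= 0) stopf("z_threshold must be positive")
  if (mode == "nogo") {
    st_n <- condition_stats(ep, "correct_nogo")
    st_g <- condition_stats(ep, "correct_go")
    z <- pointwise_z(st_n, st_g)
    ranges <- extract_ranges(z, st_n, st_g, threshold = z_threshold, mode = "nogo")
    if (is.null(median_rt_s)) median_rt_s <- median_rt(ep$events)
    win <- analysis_windows(median_rt_s)
    sel <- select_for_windows(ranges, win, c("early", "late"))
  } else {
    st_p <- condition_stats(ep, "pooled")
    z <- pointwise_z(st_p)
    ranges <- extract_ranges(z, st_p, threshold = z_threshold, mode = "visual")
    win <- analysis_windows(median_rt_s %||% 0.4)
    sel <- select_for_windows(ranges, win, "visual")
    st_n <- st_p; st_g <- NULL
  }
  if (length(exclude)) sel <- sel[!sel$ic %in% exclude, , drop = FALSE]
  structure(list(selection = sel, z = z, stats_a = st_n, stats_b = st_g,
                 windows = win, mode = mode, z_threshold = z_threshold,
                 excluded_ics = exclude, median_rt_s = median_rt_s,
                 n_units = nrow(z$z)),
            class = "ic_selection")
}

#' @export
print.ic_selection <- function(x, ...) {
  cat(sprintf("<ic_selection> mode %s, |Z| > %g, %d ICs scanned (%d excluded as artifacts)\n",
              x$mode, x$z_threshold, x$n_units, length(x$excluded_ics)))
  if (!nrow(x$selection)) {
    cat("  no latency range selected for any window\n")
  } else {
    for (w in unique(x$selection$window)) {
      s <- x$selection[x$selection$window == w, ]
      cat(sprintf("  %s [%.3f, %.3f] s: %d range(s) on IC(s) %s\n",
                  w, x$windows[[w]][1], x$windows[[w]][2], nrow(s),
                  paste(unique(s$ic), collapse = ", ")))
    }
  }
  invisible(x)
}

#' @export
summary.ic_selection <- function(object, ...) {
  s <- object$selection
  out <- list(mode = object$mode, z_threshold = object$z_threshold,
              median_rt_s = object$median_rt_s,
              n_ranges = nrow(s),
              per_window = table(s$window),
              selection = s)
  class(out) <- "summary.ic_selection"
  out
}

#' @export
print.summary.ic_selection <- function(x, ...) {
  cat(sprintf("IC selection (%s mode), threshold |Z| > %g", x$mode, x$z_threshold))
  if (!is.null(x$median_rt_s)) cat(sprintf(", median RT %.3f s", x$median_rt_s))
  cat("\n")
  if (x$n_ranges) print(x$selection) else cat("no ranges selected\n")
  invisible(x)
}

#' Plot the reliability series of an IC selection
#'
#' Draws the |Z| trace of the strongest (or requested) ICs against the
#' threshold, shading the analysis windows and marking selected ranges.
#'
#' @param x An `ic_selection`.
#' @param ics IC indices to draw (default: ICs with selected ranges, else the
#'   3 with the largest peak |Z|).
#' @param ... Unused.
#' @export
plot.ic_selection <- function(x, ics = NULL, ...) {
  if (is.null(ics)) {
    ics <- unique(x$selection$ic)
    if (!length(ics))
      ics <- order(apply(abs(x$z$z), 1, max), decreasing = TRUE)[1:min(3, x$n_units)]
  }
  zt <- x$z$times
  zmax <- max(abs(x$z$z[ics, , drop = FALSE]), x$z_threshold * 2)
  graphics::plot(NA, xlim = range(zt), ylim = c(0, zmax), xlab = "time (s)",
                 ylab = "|Z|", main = sprintf("pointwise reliability (%s)", x$mode))
  cols <- c(early = grDevices::adjustcolor("gold", 0.3),
            late = grDevices::adjustcolor("firebrick", 0.2),
            visual = grDevices::adjustcolor("steelblue", 0.25))
  for (w in names(x$windows))
    if (w %in% unique(c(x$selection$window, if (x$mode == "visual") "visual"
                        else c("early", "late"))))
      graphics::rect(x$windows[[w]][1], 0, x$windows[[w]][2], zmax,
                     col = cols[[w]], border = NA)
  for (i in seq_along(ics))
    graphics::lines(zt, abs(x$z$z[ics[i], ]), col = i)
  graphics::abline(h = x$z_threshold, lty = 2)
  if (nrow(x$selection))
    graphics::segments(x$selection$t_on, x$z_threshold, x$selection$t_off,
                       x$z_threshold, lwd = 3,
                       col = match(x$selection$ic, ics))
  graphics::legend("topright", legend = paste0("IC", ics), col = seq_along(ics),
                   lty = 1, bty = "n")
  invisible(x)
}
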