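#' Construct a trial event table
#'
#' An event table holds one row per stimulus with its onset (seconds from run
#' start), trial type (`Go`/`Nogo`), the behavioural response category and,
#' where a button press occurred, the response time. It is the single source
#' of truth for trial typing: epoching, feature extraction and regressor
#' construction all key off it.
#'
#' The response category is fully determined by trial type and the presence of
#' a button press: a press on a Go trial is `correct`, no press on a Go trial
#' is an `omission`, a press on a Nogo trial is a `commission` error, and no
#' press on a Nogo trial is `correct`. A response time is present if and only
#' if a press occurred.
#'
#' @param onset Numeric vector, strictly increasing onsets in seconds.
#' @param trial_type Character vector, `"Go"` or `"Nogo"`.
#' @param response_time Numeric vector, response time in seconds, `NA` where
#'   no button was pressed.
#' @param duration Stimulus duration in seconds (default 0.5).
#' @return A data frame of class `event_table` with columns `onset`,
#'   `duration`, `trial_type`, `response_time`, `response` and `accuracy`.
#' @export
event_table <- function(onset, trial_type, response_time = rep(NA_real_, length(onset)),
                        duration = 0.5) {
  n <- length(onset)
  if (length(trial_type) != n || length(response_time) != n)
    stopf("onset, trial_type and response_time must have equal length")
  if (n > 1 && any(diff(onset) <= 0))
    stopf("event onsets must be strictly increasing")
  if (!all(trial_type %in% c("Go", "Nogo")))
    stopf("trial_type must be 'Go' or 'Nogo'")
  pressed <- !is.na(response_time)
  response <- ifelse(trial_type == "Go",
                     ifelse(pressed, "correct", "omission"),
                     ifelse(pressed, "commission", "correct"))
  tab <- data.frame(
    onset = as.numeric(onset),
    duration = rep_len(as.numeric(duration), n),
    trial_type = trial_type,
    response_time = as.numeric(response_time),
    response = response,
    accuracy = as.integer(response == "correct"),
    stringsAsFactors = FALSE
  )
  class(tab) <- c("event_table", "data.frame")
  tab
}

validate_events <- function(events) {
  if (!inherits(events, "data.frame"))
    stopf("events must be a data frame")
  need <- c("onset", "trial_type", "response")
  miss <- setdiff(need, names(events))
  if (length(miss))
    stopf("events table lacks column(s): %s", paste(miss, collapse = ", "))
  if (nrow(events) > 1 && any(diff(events$onset) <= 0))
    stopf("event onsets must be strictly increasing")
  invisible(events)
}

#' Read and write BIDS-style event tables
#'
#' Tab-separated files with columns `onset`, `duration`, `trial_type`,
#' `response_time` (`n/a` where no press occurred) and `response`. On reading,
#' the `response` and `accuracy` columns are (re)derived from trial type and
#' response-time presence, so the press/no-press structure is the authoritative
#' record.
#'
#' @param path File path of the `.tsv` events file.
#' @return `read_events()` returns an [event_table]; `write_events()` returns
#'   `path` invisibly.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stopf("events file not found: %s", path)
  raw <- utils::read.delim(path, sep = "\t", na.strings = c("n/a", "NA"),
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("onset", "trial_type", "response_time")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stopf("events file %s lacks column(s): %s", path, paste(miss, collapse = ", "))
  if (nrow(raw) > 1 && any(diff(raw$onset) <= 0))
    stopf("events file %s has non-monotone onsets", path)
  event_table(onset = raw$onset, trial_type = raw$trial_type,
              response_time = raw$response_time,
              duration = raw$duration %||% 0.5)
}

#' @rdname read_events
#' @param events An [event_table].
#' @export
write_events <- function(events, path) {
  validate_events(events)
  out <- events[, c("onset", "duration", "trial_type", "response_time", "response")]
  out$response_time <- ifelse(is.na(out$response_time), "n/a",
                              format(out$response_time, digits = 15, trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cross-check EEG trigger codes against the events table
#'
#' The events file is the single source of truth for trial typing; this
#' utility compares the recording's stimulus triggers with the table and
#' reports mismatches (position or code) without failing, so discrepancies
#' are visible but never fatal.
#'
#' @param rec A [recording].
#' @param events An [event_table].
#' @param code_map Named character vector mapping trial types to trigger
#'   codes.
#' @param tol_s Maximum onset discrepancy in seconds.
#' @return Invisibly, a data frame of mismatches (zero rows when consistent);
#'   mismatches are also reported via `message()`.
#' @export
check_triggers <- function(rec, events, code_map = c(Go = "S  1", Nogo = "S  2"),
                           tol_s = 0.005) {
  stopifnot(inherits(rec, "recording"))
  validate_events(events)
  stim <- rec$triggers[rec$triggers$code %in% code_map, , drop = FALSE]
  bad <- list()
  for (i in seq_len(nrow(events))) {
    want_code <- code_map[[events$trial_type[i]]]
    t_ev <- events$onset[i]
    j <- which(abs(stim$sample / rec$sfreq - t_ev) <= tol_s)
    if (!length(j)) {
      bad[[length(bad) + 1L]] <- data.frame(
        row = i, onset = t_ev, problem = "no trigger at onset")
    } else if (!any(stim$code[j] == want_code)) {
      bad[[length(bad) + 1L]] <- data.frame(
        row = i, onset = t_ev,
        problem = sprintf("code %s, expected %s", stim$code[j[1]], want_code))
    }
  }
  out <- if (length(bad)) do.call(rbind, bad) else
    data.frame(row = integer(0), onset = numeric(0), problem = character(0))
  if (nrow(out))
    message(sprintf("check_triggers: %d mismatch(es); first: row %d (%s)",
                    nrow(out), out$row[1], out$problem[1]))
  invisible(out)
}
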