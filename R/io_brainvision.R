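#' Construct a continuous multichannel recording
#'
#' The in-memory container for continuous EEG: a channels-by-samples amplitude
#' matrix in microvolts plus sampling rate, channel labels/kinds and trigger
#' events. Sample indices are 0-based throughout (`seconds = sample / sfreq`),
#' and all intervals are half-open `[start, end)`.
#'
#' Channel kinds are inferred from labels unless given explicitly: labels
#' matching `ECG` (case-insensitive) are tagged `ECG`, labels matching `EOG`
#' are tagged `EOG`, everything else is `scalp`.
#'
#' @param data Numeric matrix, channels x samples, microvolts.
#' @param sfreq Sampling frequency in Hz.
#' @param channel_labels Character vector of channel names.
#' @param channel_kinds Optional character vector (`"scalp"`, `"EOG"`,
#'   `"ECG"`); inferred from labels when `NULL`.
#' @param triggers Data frame with columns `sample` (0-based index) and
#'   `code` (character), or `NULL`.
#' @return An object of class `recording`.
#' @export
recording <- function(data, sfreq, channel_labels = NULL, channel_kinds = NULL,
                      triggers = NULL) {
  data <- as.matrix(data)
  if (!is_scalar_num(sfreq) || sfreq <= 0) stopf("sfreq must be a positive number")
  nch <- nrow(data)
  if (nch < 1L) stopf("recording needs at least one channel")
  if (is.null(channel_labels)) channel_labels <- paste0("Ch", seq_len(nch))
  if (length(channel_labels) != nch)
    stopf("channel_labels length (%d) != number of rows (%d)",
          length(channel_labels), nch)
  if (is.null(channel_kinds)) channel_kinds <- infer_channel_kinds(channel_labels)
  if (!all(channel_kinds %in% c("scalp", "EOG", "ECG")))
    stopf("channel_kinds must be 'scalp', 'EOG' or 'ECG'")
  if (is.null(triggers))
    triggers <- data.frame(sample = integer(0), code = character(0),
                           stringsAsFactors = FALSE)
  triggers$sample <- as.integer(triggers$sample)
  if (nrow(triggers) && (any(triggers$sample < 0L) ||
                         any(triggers$sample >= ncol(data))))
    stopf("trigger sample indices must lie in [0, n_samples)")
  rownames(data) <- channel_labels
  structure(list(data = data, sfreq = sfreq,
                 channel_labels = channel_labels,
                 channel_kinds = channel_kinds,
                 triggers = triggers),
            class = "recording")
}

infer_channel_kinds <- function(labels) {
  kinds <- rep("scalp", length(labels))
  kinds[grepl("ECG", labels, ignore.case = TRUE)] <- "ECG"
  kinds[grepl("EOG", labels, ignore.case = TRUE)] <- "EOG"
  kinds
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$sfreq, ncol(x$data) / x$sfreq))
  tab <- table(x$channel_kinds)
  cat("  channels:", paste(sprintf("%d %s", tab, names(tab)), collapse = ", "), "\n")
  cat(sprintf("  triggers: %d\n", nrow(x$triggers)))
  invisible(x)
}

# --- BrainVision triplet (.vhdr / .vmrk / .eeg) ------------------------------

parse_bv_ini <- function(lines) {
  sec <- NULL
  out <- list()
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[.*\\]$", ln)) {
      sec <- gsub("^\\[|\\]$", "", ln)
      out[[sec]] <- list()
    } else if (grepl("=", ln, fixed = TRUE) && !is.null(sec)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      out[[sec]][[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
    }
  }
  out
}

#' Read a BrainVision EEG recording
#'
#' Parses the header (`.vhdr`), marker (`.vmrk`) and binary data (`.eeg`)
#' triplet into a [recording]. Amplitudes are returned in microvolts (channel
#' resolutions and units are applied); markers become trigger events with
#' 0-based sample indices. Supported binary formats are `IEEE_FLOAT_32` and
#' `INT_16`, in multiplexed or vectorized orientation.
#'
#' @param path Path to the `.vhdr` header file.
#' @param channel_kinds Optional explicit channel-kind vector overriding
#'   label-based inference.
#' @return A [recording].
#' @export
read_recording <- function(path, channel_kinds = NULL) {
  if (!file.exists(path)) stopf("header file not found: %s", path)
  hdr <- parse_bv_ini(readLines(path, warn = FALSE))
  ci <- hdr[["Common Infos"]]
  if (is.null(ci)) stopf("%s: no [Common Infos] section; not a BrainVision header", path)
  dir <- dirname(path)
  data_file <- file.path(dir, ci$DataFile)
  marker_file <- if (!is.null(ci$MarkerFile)) file.path(dir, ci$MarkerFile) else NULL
  if (!file.exists(data_file))
    stopf("data file %s referenced by %s is missing", ci$DataFile, path)
  nch <- as.integer(ci$NumberOfChannels)
  if (is.na(nch) || nch < 1L) stopf("%s: invalid NumberOfChannels", path)
  sfreq <- 1e6 / as.numeric(ci$SamplingInterval)  # microseconds per sample

  chs <- hdr[["Channel Infos"]]
  labels <- character(nch); resolution <- rep(1, nch); units <- rep("µV", nch)
  for (i in seq_len(nch)) {
    entry <- chs[[sprintf("Ch%d", i)]]
    if (is.null(entry)) stopf("%s: missing Channel Infos entry Ch%d", path, i)
    parts <- strsplit(entry, ",", fixed = TRUE)[[1]]
    labels[i] <- parts[1]
    if (length(parts) >= 3 && nzchar(parts[3])) resolution[i] <- as.numeric(parts[3])
    if (length(parts) >= 4 && nzchar(parts[4])) units[i] <- parts[4]
  }
  scale <- vapply(units, function(u) switch(u,
    "µV" = 1, "uV" = 1, "mV" = 1e3, "V" = 1e6,
    stopf("unknown channel unit '%s'", u)), numeric(1))

  fmt <- toupper(ci$DataFormat %||% "BINARY")
  if (fmt != "BINARY") stopf("only BINARY DataFormat is supported, got %s", fmt)
  orientation <- toupper(ci$DataOrientation %||% "MULTIPLEXED")
  bin <- toupper(hdr[["Binary Infos"]]$BinaryFormat %||% "IEEE_FLOAT_32")
  sz <- file.info(data_file)$size
  if (bin == "IEEE_FLOAT_32") {
    n_total <- sz / 4
    raw_vals <- readBin(data_file, "numeric", n = n_total, size = 4, endian = "little")
  } else if (bin == "INT_16") {
    n_total <- sz / 2
    raw_vals <- readBin(data_file, "integer", n = n_total, size = 2,
                        signed = TRUE, endian = "little")
  } else stopf("unsupported BinaryFormat %s", bin)
  n_samp <- length(raw_vals) %/% nch
  raw_vals <- raw_vals[seq_len(n_samp * nch)]
  dat <- if (orientation == "MULTIPLEXED")
    matrix(raw_vals, nrow = nch) else t(matrix(raw_vals, ncol = nch))
  dat <- dat * (resolution * scale)

  triggers <- NULL
  if (!is.null(marker_file)) {
    if (!file.exists(marker_file))
      stopf("marker file %s referenced by %s is missing", ci$MarkerFile, path)
    mk <- parse_bv_ini(readLines(marker_file, warn = FALSE))[["Marker Infos"]]
    if (length(mk)) {
      rows <- lapply(mk, function(v) strsplit(v, ",", fixed = TRUE)[[1]])
      triggers <- data.frame(
        # BrainVision marker positions are 1-based data points
        sample = vapply(rows, function(p) as.integer(p[3]) - 1L, integer(1)),
        code = vapply(rows, function(p) p[2], character(1)),
        stringsAsFactors = FALSE)
      triggers <- triggers[order(triggers$sample), , drop = FALSE]
      rownames(triggers) <- NULL
    }
  }
  recording(dat, sfreq = sfreq, channel_labels = labels,
            channel_kinds = channel_kinds, triggers = triggers)
}

#' Write a recording as a BrainVision triplet
#'
#' Writes `.vhdr`, `.vmrk` and IEEE-float-32 multiplexed `.eeg` files. The
#' reader/writer pair round-trips amplitudes to single precision and markers
#' exactly.
#'
#' @param rec A [recording].
#' @param path Path of the `.vhdr` file to create; companion files take the
#'   same stem.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  stem <- sub("\\.vhdr$", "", path)
  eeg_file <- paste0(stem, ".eeg"); vmrk_file <- paste0(stem, ".vmrk")
  nch <- nrow(rec$data)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", basename(eeg_file)),
    paste0("MarkerFile=", basename(vmrk_file)),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nch),
    sprintf("SamplingInterval=%.10g", 1e6 / rec$sfreq),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nch), rec$channel_labels))
  writeLines(hdr, path, useBytes = TRUE)
  mk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
          "[Marker Infos]",
          "Mk1=New Segment,,1,1,0")
  if (nrow(rec$triggers))
    mk <- c(mk, sprintf("Mk%d=Stimulus,%s,%d,1,0",
                        seq_len(nrow(rec$triggers)) + 1L,
                        rec$triggers$code, rec$triggers$sample + 1L))
  writeLines(mk, vmrk_file, useBytes = TRUE)
  con <- file(eeg_file, "wb")
  on.exit(close(con))
  writeBin(as.numeric(rec$data), con, size = 4, endian = "little")
  invisible(path)
}

#' Persist a run container
#'
#' Intermediate results (recording, decomposition, selections, fit metadata)
#' are cached as a single serialized R object per run.
#'
#' @param x Any R object (typically a named list of stage outputs).
#' @param path Destination file.
#' @export
write_container <- function(x, path) { saveRDS(x, path); invisible(path) }

#' @rdname write_container
#' @export
read_container <- function(path) readRDS(path)
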