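#' Construct a 4D BOLD volume series
#'
#' @param data 4D numeric array `(x, y, z, t)` of BOLD intensities.
#' @param tr_s Repetition time in seconds.
#' @param n_discard Number of leading volumes already discarded (bookkeeping;
#'   scan times are `k * tr_s` for `k = 0, ..., t-1` on the analyzed series).
#' @return An object of class `volume_series`.
#' @export
volume_series <- function(data, tr_s, n_discard = 0L) {
  if (length(dim(data)) != 4L) stopf("volume data must be a 4D array")
  if (!is_scalar_num(tr_s) || tr_s <= 0) stopf("tr_s must be positive")
  if (dim(data)[4] < 1L) stopf("need at least one volume")
  structure(list(data = data, tr_s = tr_s, n_discard = as.integer(n_discard)),
            class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_series> %dx%dx%d voxels, %d volumes, TR = %g s (%d discarded)\n",
              d[1], d[2], d[3], d[4], x$tr_s, x$n_discard))
  invisible(x)
}

#' Scan acquisition times of a volume series
#'
#' Volume acquisition onsets on the run clock, `k * TR` for the analyzed
#' volumes (leading discarded volumes shift the origin).
#' @param vs A [volume_series].
#' @return Numeric vector of times in seconds.
#' @export
scan_times <- function(vs) {
  (vs$n_discard + seq_len(dim(vs$data)[4]) - 1) * vs$tr_s
}

#' Read and write 4D NIfTI volumes
#'
#' Thin wrappers around RNifti preserving voxel data, affine and TR. Reading a
#' 3D-only image is an error: the pipeline operates on time series.
#'
#' @param path NIfTI file (`.nii` / `.nii.gz`).
#' @param n_discard Leading volumes to drop on read (equilibration scans).
#' @return `read_volumes()` returns a [volume_series].
#' @export
read_volumes <- function(path, n_discard = 0L) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L) stopf("%s is %dD; a 4D BOLD series is required", path, length(d))
  tr <- RNifti::pixdim(img)[4]
  if (!is.finite(tr) || tr <= 0) stopf("%s: no valid TR in pixdim[4]", path)
  dat <- array(as.numeric(img), dim = d)
  n_discard <- as.integer(n_discard)
  if (n_discard >= d[4]) stopf("n_discard (%d) >= number of volumes (%d)", n_discard, d[4])
  if (n_discard > 0L) dat <- dat[, , , -(seq_len(n_discard)), drop = FALSE]
  volume_series(dat, tr_s = tr, n_discard = n_discard)
}

#' @rdname read_volumes
#' @param vs A [volume_series].
#' @export
write_volumes <- function(vs, path) {
  stopifnot(inherits(vs, "volume_series"))
  img <- RNifti::asNifti(vs$data)
  pd <- RNifti::pixdim(img)
  pd[4] <- vs$tr_s
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}
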