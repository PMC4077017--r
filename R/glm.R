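#' Discrete cosine high-pass basis
#'
#' Nuisance columns spanning fluctuations slower than the cutoff period
#' (default 128 s), excluding the constant: the first
#' `floor(2 * n_vols * tr_s / cutoff_s)` non-constant DCT-II functions.
#' Including them in the design is equivalent to high-pass filtering both
#' data and regressors while keeping ordinary least squares exact.
#'
#' @param n_vols Number of analyzed volumes.
#' @param tr_s Repetition time (s).
#' @param cutoff_s High-pass cutoff period (s).
#' @return Matrix `n_vols x K` (possibly zero columns), mutually orthogonal.
#' @export
highpass_basis <- function(n_vols, tr_s, cutoff_s = 128) {
  K <- floor(2 * n_vols * tr_s / cutoff_s)
  t <- 0:(n_vols - 1)
  if (K < 1L) return(matrix(0, n_vols, 0))
  b <- vapply(seq_len(K), function(r)
    sqrt(2 / n_vols) * cos(pi * (2 * t + 1) * r / (2 * n_vols)),
    numeric(n_vols))
  colnames(b) <- paste0("cos", seq_len(K))
  b
}

#' Assemble a first-level design matrix
#'
#' Columns: condition onset regressors, one EEG-derived regressor (already
#' resampled/normalized/convolved/orthogonalized), the discrete cosine
#' high-pass set, and an intercept.
#'
#' @param onset_regressors Matrix from [build_onset_regressors()].
#' @param eeg Numeric EEG-derived regressor (or `NULL`).
#' @param tr_s Repetition time (s).
#' @param highpass_s High-pass cutoff period, or `NULL` to omit.
#' @return A list of class `design_matrix` with `X`, `column names`, and the
#'   index of the EEG column.
#' @export
build_design <- function(onset_regressors, eeg = NULL, tr_s,
                         highpass_s = 128) {
  n <- nrow(onset_regressors)
  X <- onset_regressors
  if (!is.null(eeg)) {
    if (length(eeg) != n) stopf("EEG regressor length mismatch")
    X <- cbind(X, eeg = eeg)
  }
  if (!is.null(highpass_s)) X <- cbind(X, highpass_basis(n, tr_s, highpass_s))
  X <- cbind(X, intercept = rep(1, n))
  structure(list(X = X, names = colnames(X),
                 eeg_col = if (!is.null(eeg)) which(colnames(X) == "eeg") else NA_integer_),
            class = "design_matrix")
}

#' Voxelwise first-level GLM
#'
#' Ordinary least squares per voxel. Returns beta, t and Z images for the
#' requested contrast column (by default the EEG regressor).
#'
#' @param bold A [volume_series].
#' @param design A [build_design()] object or a plain matrix.
#' @param mask Logical 3D array of voxels to fit (`NULL`: all).
#' @param contrast Column name or index of the effect of interest.
#' @return A list of class `stat_map`: 3D arrays `beta`, `t`, `z`, plus `df`
#'   and the contrast name.
#' @export
fit_first_level <- function(bold, design, mask = NULL, contrast = "eeg") {
  stopifnot(inherits(bold, "volume_series"))
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  dims <- dim(bold$data)
  n <- dims[4]
  if (nrow(X) != n)
    stopf("design rows (%d) != analyzed volumes (%d)", nrow(X), n)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stopf("design matrix is rank deficient; collinear column(s): %s",
          paste(bad, collapse = ", "))
  }
  ci <- if (is.character(contrast)) match(contrast, colnames(X)) else contrast
  if (is.na(ci)) stopf("contrast column '%s' not in design", contrast)
  Y <- t(matrix(bold$data, prod(dims[1:3]), n))  # time x voxels
  if (!is.null(mask)) {
    vox <- which(as.vector(mask))
    Y <- Y[, vox, drop = FALSE]
  } else vox <- seq_len(prod(dims[1:3]))
  beta <- qr.coef(qrX, Y)
  res <- Y - X %*% beta
  df <- n - qrX$rank
  sigma2 <- colSums(res^2) / df
  XtXinv <- solve(crossprod(X))
  se <- sqrt(XtXinv[ci, ci] * sigma2)
  tval <- ifelse(se > 0, beta[ci, ] / se, 0)
  zval <- stats::qnorm(stats::pt(tval, df))
  zval[is.infinite(zval)] <- sign(zval[is.infinite(zval)]) * 8
  mk <- function(v) { a <- array(0, dims[1:3]); a[vox] <- v; a }
  structure(list(beta = mk(beta[ci, ]), t = mk(tval), z = mk(zval),
                 df = df, contrast = colnames(X)[ci] %||% as.character(ci)),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> contrast '%s', df = %d, t in [%.2f, %.2f]\n",
              x$contrast, x$df, min(x$t), max(x$t)))
  invisible(x)
}

#' Average run-level contrast images into a subject image
#'
#' @param images List of 3D arrays (one per run) on the same grid.
#' @return Voxelwise arithmetic mean, a 3D array.
#' @export
average_runs <- function(images) {
  stopifnot(is.list(images), length(images) >= 1L)
  d <- dim(images[[1]])
  for (im in images)
    if (!identical(dim(im), d)) stopf("contrast images are on different grids")
  Reduce(`+`, images) / length(images)
}

#' Voxelwise group-level t statistics
#'
#' One-sample t across subject images, or a paired t computed as the
#' one-sample t of the voxelwise difference images.
#'
#' @param images List of 3D subject arrays (one-sample mode).
#' @param images_b Second aligned list for paired mode.
#' @param mode `"one_sample"` or `"paired"`.
#' @return A `stat_map` with `t` and `df = n - 1`.
#' @export
group_stats <- function(images, images_b = NULL,
                        mode = c("one_sample", "paired")) {
  mode <- match.arg(mode)
  if (mode == "paired") {
    if (is.null(images_b) || length(images_b) != length(images))
      stopf("paired mode needs two aligned image lists")
    images <- Map(function(a, b) a - b, images, images_b)
  }
  n <- length(images)
  if (n < 3L) stopf("need >= 3 subjects, got %d", n)
  d <- dim(images[[1]])
  Y <- vapply(images, as.vector, numeric(prod(d)))
  m <- rowMeans(Y)
  s <- sqrt(apply(Y, 1, stats::var) / n)
  tval <- ifelse(s > 0, m / s, 0)
  structure(list(beta = array(m, d), t = array(tval, d),
                 z = array(stats::qnorm(stats::pt(tval, n - 1)), d),
                 df = n - 1L, contrast = mode),
            class = "stat_map")
}

# 26-connectivity neighbor offsets
neighbor_offsets <- function(connectivity = 26L) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  if (connectivity == 6L) g <- g[abs(g$dx) + abs(g$dy) + abs(g$dz) == 1, ]
  else if (connectivity == 18L) g <- g[abs(g$dx) + abs(g$dy) + abs(g$dz) <= 2, ]
  as.matrix(g)
}

# Label connected components of a logical 3D array (BFS flood fill).
label_components <- function(bin, connectivity = 26L) {
  d <- dim(bin)
  lab <- array(0L, d)
  offs <- neighbor_offsets(connectivity)
  cur <- 0L
  idx_all <- which(bin)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      co <- arrayInd(v, d)
      nb <- sweep(offs, 2, as.integer(co), `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      li <- nb[, 1] + (nb[, 2] - 1L) * d[1] + (nb[, 3] - 1L) * d[1] * d[2]
      li <- li[bin[li] & lab[li] == 0L]
      if (length(li)) { lab[li] <- cur; queue <- c(queue, li) }
    }
  }
  lab
}

#' Cluster-extent thresholding of a statistic map
#'
#' Voxels exceeding the t value for the uncorrected voxelwise p (one-sided
#' for directional contrasts, two-sided otherwise) are grouped into
#' connected components (26-connectivity by default); clusters smaller than
#' `k` voxels are removed.
#'
#' @param map A `stat_map`.
#' @param p_voxel Uncorrected voxelwise p threshold.
#' @param k Minimum cluster extent in voxels.
#' @param connectivity 6, 18 or 26.
#' @param direction `"pos"`, `"neg"` or `"two_sided"`.
#' @return A list of class `cluster_table`: data frame `clusters` (size,
#'   peak t, peak voxel indices), the label array and the t threshold.
#' @export
cluster_threshold <- function(map, p_voxel = 0.005, k = 20L,
                              connectivity = 26L,
                              direction = c("pos", "neg", "two_sided")) {
  direction <- match.arg(direction)
  stopifnot(inherits(map, "stat_map"))
  tcrit <- stats::qt(1 - if (direction == "two_sided") p_voxel / 2 else p_voxel,
                     df = map$df)
  bin <- switch(direction,
                pos = map$t > tcrit,
                neg = map$t < -tcrit,
                two_sided = abs(map$t) > tcrit)
  lab <- label_components(bin, connectivity)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= k)
  rows <- lapply(keep, function(cl) {
    vox <- which(lab == cl)
    tv <- map$t[vox]
    pk <- vox[which.max(abs(tv))]
    co <- arrayInd(pk, dim(map$t))
    data.frame(cluster = cl, size = sizes[cl], peak_t = tv[which.max(abs(tv))],
               x = co[1], y = co[2], z = co[3])
  })
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster = integer(0), size = integer(0), peak_t = numeric(0),
               x = integer(0), y = integer(0), z = integer(0))
  clusters <- clusters[order(-clusters$size), , drop = FALSE]
  rownames(clusters) <- NULL
  lab[!lab %in% keep] <- 0L
  structure(list(clusters = clusters, labels = lab, t_threshold = tcrit,
                 p_voxel = p_voxel, k = k),
            class = "cluster_table")
}

#' @export
print.cluster_table <- function(x, ...) {
  cat(sprintf("<cluster_table> t > %.3f, extent >= %d: %d cluster(s)\n",
              x$t_threshold, x$k, nrow(x$clusters)))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

#' Isotropic Gaussian smoothing of a volume series
#'
#' Optional pre-step for synthetic volumes mirroring standard spatial
#' smoothing; separable 1D Gaussian convolution per axis.
#'
#' @param vs A [volume_series].
#' @param fwhm_vox Full width at half maximum in voxels.
#' @return A smoothed [volume_series].
#' @export
smooth_volumes <- function(vs, fwhm_vox = 2) {
  sigma <- fwhm_vox / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(-r:r, sd = sigma); kern <- kern / sum(kern)
  out <- vs$data
  for (t in seq_len(dim(out)[4])) {
    a <- out[, , , t]
    for (ax in 1:3) {
      perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
      b <- aperm(a, perm)
      d <- dim(b)
      m <- matrix(b, d[1])
      pad <- rbind(m[rev(seq_len(r)), , drop = FALSE], m,
                   m[nrow(m) - seq_len(r) + 1L, , drop = FALSE])
      sm <- stats::filter(pad, kern, sides = 2)[r + seq_len(d[1]), , drop = FALSE]
      b <- array(sm, d)
      a <- aperm(b, order(perm))
    }
    out[, , , t] <- a
  }
  vs$data <- out
  vs
}
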