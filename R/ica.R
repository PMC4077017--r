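#' Fit a square ICA unmixing matrix by extended infomax
#'
#' Estimates a square unmixing matrix `W` for the continuous multichannel
#' data of one run by the extended infomax algorithm: natural-gradient
#' maximization of the information-maximization contrast with a per-component
#' sub-/super-Gaussian switch estimated from the running kurtosis sign, after
#' PCA sphering. IC activations for any sample are then `W %*% (data -
#' center)` without retraining. Training is full-batch and fully
#' deterministic; `seed` is stored in the fit metadata for provenance.
#'
#' @param rec A [recording], or a plain channels-by-samples matrix.
#' @param seed Seed recorded with the fit (the iteration itself is
#'   deterministic).
#' @param max_iter Maximum number of training iterations.
#' @param tol Convergence tolerance on the relative weight change per
#'   iteration.
#' @param lrate Initial learning rate (grown on progress, halved on
#'   divergence).
#' @param n_train Cap on the number of (evenly spaced) samples used for
#'   training; defaults to `max(25000, 50 * n_channels^2)`.
#' @param block Unused; retained for call compatibility.
#' @return An object of class `decomposition` with elements `unmixing` (W,
#'   channels x channels, includes sphering), `mixing` (its inverse),
#'   `center` (channel means), `ic_labels`, `artifact_flags` and `meta`
#'   (iterations, final weight change, seed, convergence flag).
#' @export
fit_unmixing <- function(rec, seed = 1L, max_iter = 2000L, tol = 1e-6,
                         lrate = NULL, n_train = NULL, block = NULL) {
  X <- if (inherits(rec, "recording")) rec$data else as.matrix(rec)
  nch <- nrow(X); n <- ncol(X)
  if (n < 5L * nch * nch)
    warning(sprintf(
      "only %d samples for %d channels; ICA may be poorly determined", n, nch),
      call. = FALSE)
  center <- rowMeans(X)
  Xc <- X - center
  # PCA sphering; near-zero eigenvalues are floored with a warning (reduced
  # effective rank)
  C <- tcrossprod(Xc) / n
  eg <- eigen(C, symmetric = TRUE)
  lam <- eg$values
  floor_ev <- max(lam) * 1e-12
  if (any(lam < floor_ev)) {
    warning(sprintf("data numerically rank-deficient (%d/%d usable dimensions); eigenvalues floored",
                    sum(lam >= floor_ev), nch), call. = FALSE)
    lam <- pmax(lam, floor_ev)
  }
  sphere <- eg$vectors %*% diag(1 / sqrt(lam), nch) %*% t(eg$vectors)
  Xw <- sphere %*% Xc

  # Training operates full-batch on an evenly spaced subsample (continuous
  # EEG is heavily oversampled relative to the number of mixing parameters),
  # which makes the natural-gradient iteration deterministic and smoothly
  # convergent: at the contrast's fixed point the batch gradient vanishes
  # exactly, so the weight change can be driven below `tol`.
  if (is.null(n_train)) n_train <- max(25000L, 50L * nch * nch)
  n_train <- min(n, n_train)
  sub <- unique(round(seq(1L, n, length.out = n_train)))
  Xt <- Xw[, sub, drop = FALSE]
  m <- ncol(Xt)
  if (is.null(lrate)) lrate <- 0.1
  W <- diag(nch)
  I <- diag(nch)
  signs <- rep(1, nch)          # +1 super-Gaussian, -1 sub-Gaussian
  wchange <- Inf
  iter <- 0L
  # divergence guard: remember the lowest-gradient iterate; when the gradient
  # norm grows well past it (a slowly amplifying unstable mode under a too
  # large step), restart from there at half the step size
  g_best <- Inf; W_best <- W; lrate_min <- 1e-6; stall <- 0L
  repeat {
    iter <- iter + 1L
    u <- W %*% Xt
    tu <- tanh(u)
    if (iter %% 3L == 1L) {
      kurt <- rowMeans(u^4) / rowMeans(u^2)^2 - 3
      # dead zone: near-Gaussian components keep their previous class, so the
      # switch cannot flap between sub- and super-Gaussian from iteration to
      # iteration
      s_new <- ifelse(kurt > 0.05, 1, ifelse(kurt < -0.05, -1, signs))
      if (any(s_new != signs)) g_best <- Inf
      signs <- s_new
    }
    G <- I - ((signs * tu) %*% t(u)) / m - (u %*% t(u)) / m
    gnorm <- sqrt(sum(G^2))
    if (!is.finite(gnorm) || gnorm > 3 * g_best) {
      lrate <- lrate * 0.5
      W <- W_best
      g_best <- Inf
      if (lrate < lrate_min) break
      next
    }
    if (gnorm < g_best) { g_best <- gnorm; W_best <- W; stall <- 0L }
    else stall <- stall + 1L
    dW <- lrate * G %*% W
    W <- W + dW
    wchange <- sqrt(sum(dW^2) / sum(W^2))
    # when the gradient stops improving (limit cycle at the current step
    # size) anneal the step so the iteration settles
    lrate <- if (stall > 20L) lrate * 0.99 else min(lrate * 1.02, 0.3)
    if (wchange < tol || iter >= max_iter) break
  }
  converged <- wchange < tol
  if (!converged)
    stopf("extended infomax did not converge: wchange = %.3g after %d iterations (tol %.1g); increase max_iter",
          wchange, iter, tol)
  unmix <- W %*% sphere
  mix <- solve(unmix)
  structure(list(
    unmixing = unmix, mixing = mix, center = center,
    ic_labels = paste0("IC", seq_len(nch)),
    artifact_flags = integer(0),
    meta = list(iterations = iter, wchange = wchange, seed = seed,
                converged = converged, n_train = m)),
    class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("<decomposition> %d ICs (extended infomax, %d passes, seed %d)\n",
              nrow(x$unmixing), x$meta$iterations, x$meta$seed))
  if (length(x$artifact_flags))
    cat("  artifact ICs:", paste(x$artifact_flags, collapse = ", "), "\n")
  invisible(x)
}

#' IC activation time courses
#'
#' @param dec A `decomposition`.
#' @param rec The [recording] (or matrix) to unmix.
#' @return Matrix, ICs x samples.
#' @export
ic_activations <- function(dec, rec) {
  X <- if (inherits(rec, "recording")) rec$data else as.matrix(rec)
  dec$unmixing %*% (X - dec$center)
}
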