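# Small-cap simulation configs used across the suite. The paradigm keeps the
# full study conditions (300 trials, 29% Nogo, 1 s SOA); the EEG cap is shrunk
# to 8 channels so per-seed ICA fits stay fast while every source (inhibition,
# visual, BCG, blink) still has room to separate.
small_cfg <- function(seed, ...) {
  sim_config(seed = seed, n_channels = 8, ...)
}

# ICA settings used with the small cap: a looser (but still tight) tolerance
# and a reduced training subsample keep one fit around a second.
fit_small <- function(rec) fit_unmixing(rec, tol = 3e-4, n_train = 12000)

# Cosine similarity of a planted scalp topography with each column of an
# estimated mixing matrix (scalp rows only).
topo_match <- function(truth, dec, n_scalp) {
  topo <- truth$mixing[seq_len(n_scalp), "inhibition"]
  M <- dec$mixing[seq_len(n_scalp), , drop = FALSE]
  abs(as.numeric(topo %*% M) / (sqrt(sum(topo^2)) * sqrt(colSums(M^2))))
}

# Manually assembled condition_stats, for feeding pointwise_z with exact
# numbers.
make_stats <- function(mean, var, n, times = NULL) {
  mean <- rbind(unname(mean)); var <- rbind(unname(var))
  if (is.null(times)) times <- (seq_len(ncol(mean)) - 1) / 100
  structure(list(mean = mean, var = var, n = n, condition = "custom",
                 times = times), class = "condition_stats")
}

# Manually assembled z_series on a 100 Hz grid starting at t = 0.
make_z <- function(z, n_ref = 90, t0 = 0) {
  z <- rbind(z)
  structure(list(z = z, t = z * sqrt(n_ref), mode = "two_sample",
                 n_ref = n_ref, df = n_ref - 1L,
                 times = t0 + (seq_len(ncol(z)) - 1) / 100, infinite = FALSE),
            class = "z_series")
}
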