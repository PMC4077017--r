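test_that("paradigm generator honors trial count, grid and constraint", {
  cfg <- small_cfg(1)
  ev <- gen_paradigm(cfg)
  expect_equal(nrow(ev), 300L)
  expect_equal(ev$onset, as.numeric(0:299))
  nogo <- ev$trial_type == "Nogo"
  expect_equal(sum(nogo[-1] & nogo[-length(nogo)]), 0L)
  # degenerate rate
  ev0 <- gen_paradigm(small_cfg(2, p_nogo = 0))
  expect_true(all(ev0$trial_type == "Go"))
  # infeasible rate refused at construction
  expect_error(sim_config(seed = 1, p_nogo = 0.6), "0.5")
})

test_that("no Nogo follows a Nogo across many seeds", {
  for (s in 1:20) {
    ev <- gen_paradigm(small_cfg(s, n_trials = 200L))
    nogo <- ev$trial_type == "Nogo"
    expect_equal(sum(nogo[-1] & nogo[-length(nogo)]), 0L)
  }
})

test_that("realized Nogo fraction approaches the configured rate", {
  n_tot <- 0L; n_nogo <- 0L
  for (s in 1:100) {
    ev <- gen_paradigm(small_cfg(s, n_trials = 300L))
    n_tot <- n_tot + nrow(ev)
    n_nogo <- n_nogo + sum(ev$trial_type == "Nogo")
  }
  p_hat <- n_nogo / n_tot
  # conservative (iid) Monte-Carlo standard error; the chain's negative
  # autocorrelation makes the true SE smaller
  se <- sqrt(0.29 * 0.71 / n_tot)
  expect_lt(abs(p_hat - 0.29), 3 * se)
})

test_that("generator output is a pure function of config and seed", {
  cfg <- small_cfg(9)
  ev1 <- gen_paradigm(cfg); ev2 <- gen_paradigm(cfg)
  expect_identical(ev1, ev2)
  e1 <- gen_eeg(ev1, cfg); e2 <- gen_eeg(ev2, cfg)
  expect_identical(e1$recording$data, e2$recording$data)
  expect_identical(e1$truth$trial_amplitudes, e2$truth$trial_amplitudes)
  b1 <- gen_bold(ev1, e1$truth, cfg); b2 <- gen_bold(ev2, e2$truth, cfg)
  expect_identical(b1$volumes$data, b2$volumes$data)
})

test_that("noiseless EEG equals mixing times sources exactly", {
  cfg <- small_cfg(3, noise_sd = 0)
  ev <- gen_paradigm(cfg)
  eeg <- gen_eeg(ev, cfg)
  expect_equal(eeg$recording$data,
               eeg$truth$mixing %*% eeg$truth$sources,
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("planted Nogo-Go difference is recovered by direct epoch averaging", {
  cfg <- small_cfg(4, noise_sd = 0, go_leak = 0, bcg = FALSE, blink = FALSE)
  ev <- gen_paradigm(cfg)
  eeg <- gen_eeg(ev, cfg)
  fs <- cfg$sfreq
  # brute-force averaging of the raw channel data at the source peak
  peak_off <- round(mean(cfg$inhibition_window) * fs)
  onset_smp <- round(ev$onset * fs)
  vals <- eeg$recording$data[, onset_smp + peak_off + 1L]
  m_nogo <- rowMeans(vals[, ev$trial_type == "Nogo", drop = FALSE])
  m_go <- rowMeans(vals[, ev$trial_type == "Go", drop = FALSE])
  amps <- eeg$truth$trial_amplitudes$inhibition
  bump_peak <- max(eeg$truth$sources["inhibition", ]) /
    max(amps)  # peak of the unit bump
  expected <- eeg$truth$mixing[, "inhibition"] *
    mean(amps[ev$trial_type == "Nogo"]) * bump_peak
  expect_equal(m_nogo - m_go, expected, tolerance = 0.05, ignore_attr = TRUE)
})

test_that("gradient artifact shows a spectral line at 1/TR and harmonics", {
  cfg <- small_cfg(5, gradient = TRUE, n_volumes = 120L, bcg = FALSE,
                   blink = FALSE, noise_sd = 0.5)
  ev <- gen_paradigm(cfg)
  eeg <- gen_eeg(ev, cfg)
  ch <- eeg$recording$data[1, seq_len(120 * 225)]
  sp <- stats::spec.pgram(ch, taper = 0, plot = FALSE, detrend = TRUE)
  f0 <- 1 / cfg$tr_s / cfg$sfreq  # cycles per sample
  near <- function(f) sp$spec[which.min(abs(sp$freq - f))]
  base <- stats::median(sp$spec)
  # fundamental and first harmonic dominate the background spectrum
  expect_gt(near(f0) / base, 50)
  expect_gt(near(2 * f0) / base, 50)
})

test_that("BOLD series has the configured volume count and coupling", {
  cfg <- small_cfg(6)
  ev <- gen_paradigm(cfg)
  bold <- gen_bold(ev, NULL, cfg)
  expect_equal(dim(bold$volumes$data)[4], 157L)
  expect_equal(sum(bold$active_mask), 30L)
  expect_true(all(bold$coupling_betas[!bold$active_mask] == 0))
  expect_error(gen_bold(ev, NULL, cfg,
                        coupling_betas = array(1, cfg$grid_dim)),
               "outside")
})

test_that("zero coupling and zero noise leave only condition structure", {
  cfg <- small_cfg(7, coupling_beta = 0, bold_noise_sd = 0)
  ev <- gen_paradigm(cfg)
  bold <- gen_bold(ev, NULL, cfg)
  act <- which(bold$active_mask)
  d <- dim(bold$volumes$data)
  Y <- matrix(bold$volumes$data, prod(d[1:3]), d[4])
  # all active voxels share the same condition-driven time course
  expect_equal(Y[act[1], ], Y[act[2], ], tolerance = 1e-12)
  # inactive voxels are flat baseline
  inact <- setdiff(seq_len(prod(d[1:3])), act)[1]
  expect_equal(Y[inact, ], rep(cfg$bold_baseline, d[4]), tolerance = 1e-12)
})

test_that("noiseless active voxel regressed on the true design recovers beta", {
  cfg <- small_cfg(8, bold_noise_sd = 0, coupling_beta = 1.5)
  ev <- gen_paradigm(cfg)
  bold <- gen_bold(ev, NULL, cfg)
  amp <- bold$trial_amplitudes
  # independent reconstruction of the generative regressors by direct
  # summation of kernel lags on the oversampled grid
  tr <- cfg$tr_s; nvol <- cfg$n_volumes; dt <- tr / 16
  n_osr <- ceiling((nvol * tr + 32) / dt)
  h <- hrf_kernel(hrf_spec(), dt)
  stick <- function(onsets, w = rep(1, length(onsets))) {
    x <- numeric(n_osr)
    for (i in seq_along(onsets)) {
      j <- floor(onsets[i] / dt) + 1L
      x[j] <- x[j] + w[i]
    }
    y <- numeric(n_osr)
    for (j in which(x != 0))
      y[j:min(n_osr, j + length(h) - 1L)] <-
        y[j:min(n_osr, j + length(h) - 1L)] + x[j] * h[1:min(length(h), n_osr - j + 1L)]
    y[round((0:(nvol - 1)) * tr / dt) + 1L]
  }
  go <- ev$trial_type == "Go" & ev$response == "correct"
  nogo <- ev$trial_type == "Nogo" & ev$response == "correct"
  err <- !go & !nogo
  X <- cbind(stick(ev$onset[go]), stick(ev$onset[nogo]), stick(ev$onset[err]),
             stick(ev$onset, amp - stats::median(amp)))
  vox <- which(bold$active_mask)[1]
  co <- arrayInd(vox, cfg$grid_dim)
  y <- bold$volumes$data[co[1], co[2], co[3], ]
  beta <- stats::lm.fit(cbind(1, X), y)$coefficients
  expect_equal(unname(beta[5]), 1.5, tolerance = 1e-8)
  expect_equal(unname(beta[2]), cfg$go_effect, tolerance = 1e-8)
})

test_that("simulate_run writes the full artifact set", {
  dir <- file.path(tempdir(), "simrun")
  paths <- simulate_run(small_cfg(10, n_trials = 50L, n_volumes = 30L,
                                  grid_dim = c(6L, 6L, 6L)), dir)
  for (p in paths) expect_true(file.exists(p))
  ev <- read_events(paths$events)
  expect_equal(nrow(ev), 50L)
  rec <- read_recording(paths$eeg)
  expect_equal(nrow(rec$data), 8L)
})
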