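make_gradient_rec <- function(n_vol = 60, per = 225, fs = 100, extra = 0) {
  wave <- stats::rnorm(per, sd = 50)
  trg <- seq(0L, by = per, length.out = n_vol)
  n <- n_vol * per + 200L
  x <- numeric(n)
  for (s in trg) x[s + seq_len(per)] <- x[s + seq_len(per)] + wave
  list(x = x + extra, trg = trg, wave = wave, n = n, fs = fs)
}

test_that("a perfectly repeating artifact is removed to numerical noise", {
  set.seed(21)
  g <- make_gradient_rec()
  rec <- recording(rbind(g$x), g$fs, "C1",
                   triggers = data.frame(sample = g$trg, code = "R128"))
  out <- subtract_gradient_template(rec, window_volumes = 21)
  core <- (5 * 225):(55 * 225)
  expect_lt(max(abs(out$data[1, core])) / max(abs(g$wave)), 1e-9)
})

test_that("a slow sine riding on the artifact survives subtraction", {
  set.seed(22)
  g <- make_gradient_rec()
  sine <- sin(2 * pi * (seq_len(g$n) - 1) / g$fs / 15)  # period 15 s >> TR
  rec <- recording(rbind(g$x + sine), g$fs, "C1",
                   triggers = data.frame(sample = g$trg, code = "R128"))
  out <- subtract_gradient_template(rec, window_volumes = 21)
  core <- (11 * 225):(49 * 225)
  rel <- sqrt(mean((out$data[1, core] - sine[core])^2)) /
    sqrt(mean(sine[core]^2))
  expect_lt(rel, 0.05)
})

test_that("artifact-free noise suffers only the bounded template distortion", {
  set.seed(23)
  noise <- stats::rnorm(60 * 225 + 200)
  trg <- seq(0L, by = 225L, length.out = 60)
  rec <- recording(rbind(noise), 100, "C1",
                   triggers = data.frame(sample = trg, code = "R128"))
  out <- subtract_gradient_template(rec, window_volumes = 21)
  core <- (5 * 225):(55 * 225)
  rel <- sqrt(mean((out$data[1, core] - noise[core])^2)) /
    sqrt(mean(noise[core]^2))
  # subtracting the mean of 21 signal-free epochs distorts by ~1/sqrt(21)
  expect_lt(rel, 0.3)
})

test_that("irregular scan trigger spacing is a timing error", {
  g <- make_gradient_rec(n_vol = 30)
  trg <- g$trg; trg[10] <- trg[10] + 5L
  rec <- recording(rbind(g$x), g$fs,
                   triggers = data.frame(sample = trg, code = "R128"))
  expect_error(subtract_gradient_template(rec, trg, window_volumes = 21),
               "irregular")
})

test_that("bandpass-downsample hits the working rate, kills DC, keeps 10 Hz", {
  set.seed(24)
  fs0 <- 500; n0 <- fs0 * 60
  tt <- (0:(n0 - 1)) / fs0
  rec <- recording(rbind(3 + sin(2 * pi * 10 * tt)), fs0, "Cz",
                   triggers = data.frame(sample = 1000L, code = "S  1"))
  out <- bandpass_downsample(rec)
  expect_equal(out$sfreq, 100)
  expect_equal(out$triggers$sample, 200L)
  core <- 500:5500
  expect_lt(abs(mean(out$data[1, core])), 1e-3 * 3)
  seg <- out$data[1, core]; ts <- (core - 1) / 100
  amp <- 2 / length(seg) *
    sqrt(sum(seg * sin(2 * pi * 10 * ts))^2 + sum(seg * cos(2 * pi * 10 * ts))^2)
  expect_lt(abs(amp - 1), 0.05)
  expect_error(bandpass_downsample(rec, high = 60), "Nyquist")
})

test_that("heartbeats are recovered by template matching", {
  cfg <- small_cfg(31)
  ev <- gen_paradigm(cfg)
  eeg <- gen_eeg(ev, cfg)
  beats <- detect_artifact_events(eeg$recording, "ECG")
  planted <- eeg$truth$beat_times
  expect_equal(length(beats), length(planted))
  # detection times sit at a fixed template latency; compare after removing
  # the constant offset
  err <- beats - planted
  expect_lt(max(abs(err - stats::median(err))), 0.010)
})

test_that("a flat auxiliary channel is a detection error", {
  rec <- recording(rbind(rnorm(5000), 0), 100, c("Cz", "ECG"))
  expect_error(detect_artifact_events(rec, "ECG"), "flat")
})

test_that("the refractory rule keeps the larger of two close peaks", {
  x <- numeric(1000)
  x[300] <- 1; x[320] <- 2   # 0.2 s apart at 100 Hz
  pk <- stefi:::local_maxima(x, min_dist = 40, height = 0.5)
  expect_equal(pk, 320L)
})

test_that("BCG-locked ICs are flagged, the task IC is not", {
  cfg <- small_cfg(32)
  ev <- gen_paradigm(cfg)
  eeg <- gen_eeg(ev, cfg)
  dec <- fit_small(eeg$recording)
  beats <- detect_artifact_events(eeg$recording, "ECG")
  flags <- flag_artifact_ics(dec, eeg$recording, beats, n_null = 100,
                             seed = 99, reason = "bcg")
  act <- ic_activations(dec, eeg$recording)
  bcg_ic <- which.max(abs(stats::cor(t(act), eeg$truth$sources["bcg", ])))
  inh_ic <- which.max(abs(stats::cor(t(act), eeg$truth$sources["inhibition", ])))
  expect_true(bcg_ic %in% flags)
  expect_false(inh_ic %in% flags)
  expect_error(flag_artifact_ics(dec, eeg$recording, beats, n_null = 10,
                                 seed = 1), "n_null")
  expect_error(flag_artifact_ics(dec, eeg$recording, beats[1:5],
                                 n_null = 100, seed = 1), ">= 20")
})

test_that("an IC identical to the locked template is flagged", {
  set.seed(33)
  n <- 20000; fs <- 100
  ev_times <- seq(2, 190, by = 1.1)
  tmpl <- c(smooth_bump <- 0.5 - 0.5 * cos(2 * pi * seq_len(30) / 31))
  x1 <- numeric(n)
  for (t in ev_times) x1[round(t * fs) + seq_len(30)] <- tmpl
  dat <- rbind(x1 + rnorm(n, sd = 0.01), rnorm(n))
  dec <- structure(list(unmixing = diag(2), mixing = diag(2),
                        center = c(0, 0), ic_labels = c("IC1", "IC2"),
                        artifact_flags = integer(0), meta = list()),
                   class = "decomposition")
  rec <- recording(dat, fs, c("a", "b"))
  flags <- flag_artifact_ics(dec, rec, ev_times, n_null = 100, seed = 5)
  expect_true(1L %in% flags)
  expect_false(2L %in% flags)
})

test_that("the surrogate test flags unlocked ICs at roughly its nominal rate", {
  set.seed(34)
  hits <- 0L; tries <- 0L
  for (s in 1:4) {
    dat <- matrix(rnorm(6 * 20000), 6)
    rec <- recording(dat, 100, paste0("C", 1:6))
    dec <- structure(list(unmixing = diag(6), mixing = diag(6),
                          center = rep(0, 6), ic_labels = paste0("IC", 1:6),
                          artifact_flags = integer(0), meta = list()),
                     class = "decomposition")
    ev <- seq(2, 190, by = 1.1)
    fl <- flag_artifact_ics(dec, rec, ev, n_null = 200, seed = s)
    hits <- hits + length(fl); tries <- tries + 6L
  }
  # nominal 1% per IC; with 24 tries allow up to 3 flags (P(X>3) < 1e-4)
  expect_lte(hits, 3L)
})

test_that("removing flagged ICs reconstructs the rest of the data", {
  cfg <- small_cfg(35)
  ev <- gen_paradigm(cfg)
  eeg <- gen_eeg(ev, cfg)
  dec <- fit_small(eeg$recording)
  # removing nothing reproduces the data
  clean <- remove_ics(eeg$recording, dec, exclude = integer(0))
  expect_equal(clean$data, eeg$recording$data, tolerance = 1e-6)
  # removing one IC leaves data minus that IC's back-projection
  act <- ic_activations(dec, eeg$recording)
  clean1 <- remove_ics(eeg$recording, dec, exclude = 3L)
  manual <- eeg$recording$data - dec$mixing[, 3] %o% act[3, ]
  expect_equal(clean1$data, manual, tolerance = 1e-6)
})
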