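test_that("epochs have the 1200 ms geometry and zero baseline", {
  cfg <- small_cfg(51, n_trials = 40L)
  ev <- gen_paradigm(cfg)
  eeg <- gen_eeg(ev, cfg)
  ep <- suppressMessages(epoch_units(eeg$recording$data, ev, sfreq = 100))
  expect_equal(dim(ep$values)[3], 120L)
  expect_equal(ep$times[1], -0.2)
  bidx <- which(ep$times < 0)
  expect_equal(length(bidx), 20L)
  bl <- apply(ep$values[, , bidx, drop = FALSE], c(1, 2), mean)
  expect_lt(max(abs(bl)), 1e-9)
})

test_that("a constant signal epochs to exactly zero", {
  ev <- event_table(onset = c(1, 3, 5), trial_type = c("Go", "Nogo", "Go"),
                    response_time = c(0.4, NA, 0.5))
  tc <- matrix(7.3, 2, 700)
  ep <- epoch_units(tc, ev, sfreq = 100)
  expect_true(all(abs(ep$values) < 1e-12))
})

test_that("epoching matches a brute-force loop", {
  set.seed(52)
  ev <- event_table(onset = c(1, 2.5, 4, 6), trial_type = c("Go", "Nogo", "Go", "Go"),
                    response_time = c(0.4, NA, NA, 0.3))
  tc <- matrix(rnorm(3 * 800), 3)
  ep <- epoch_units(tc, ev, sfreq = 100)
  for (i in seq_len(4)) for (u in 1:3) {
    o <- round(ev$onset[i] * 100)
    seg <- tc[u, o + (-20:99) + 1]
    seg <- seg - mean(seg[1:20])
    expect_equal(ep$values[i, u, ], seg, tolerance = 1e-12)
  }
  expect_equal(ep$condition, c("correct_go", "correct_nogo", "omission",
                               "correct_go"))
})

test_that("events too close to the run edge are dropped, not fatal", {
  ev <- event_table(onset = c(0.05, 2, 5.95), trial_type = c("Go", "Go", "Go"),
                    response_time = c(0.3, 0.3, 0.3))
  tc <- matrix(rnorm(600), 1)
  expect_message(ep <- epoch_units(tc, ev, sfreq = 100), "dropped 2")
  expect_equal(dim(ep$values)[1], 1L)
  expect_equal(ep$trial_index, 2L)
})

test_that("condition statistics match hand and loop computations", {
  # two epochs with values 1 and 3 at a point: mean 2, unbiased var 2
  ev <- event_table(onset = c(1, 2), trial_type = c("Nogo", "Nogo"))
  tc <- matrix(0, 1, 400)
  ep <- epoch_units(tc, ev, sfreq = 100, baseline = c(-0.2, -0.1))
  ep$values[1, 1, ] <- 1; ep$values[2, 1, ] <- 3
  st <- condition_stats(ep, "correct_nogo")
  expect_equal(st$mean[1, 5], 2)
  expect_equal(st$var[1, 5], 2)
  expect_equal(st$n, 2L)
  expect_error(condition_stats(ep, "correct_go"), ">= 2")

  set.seed(53)
  ep$values <- array(rnorm(2 * 1 * 120), dim = c(2, 1, 120))
  st2 <- condition_stats(ep, "correct_nogo")
  for (j in c(1, 60, 120)) {
    expect_equal(st2$mean[1, j], mean(ep$values[, 1, j]), tolerance = 1e-12)
    expect_equal(st2$var[1, j], stats::var(ep$values[, 1, j]), tolerance = 1e-12)
  }
})

test_that("the Go/Nogo design yields four event-type averages", {
  cfg <- small_cfg(54)
  ev <- gen_paradigm(cfg)
  eeg <- gen_eeg(ev, cfg)
  ep <- suppressMessages(epoch_units(eeg$recording$data, ev, sfreq = 100))
  types <- unique(ep$condition)
  expect_setequal(types, c("correct_go", "correct_nogo", "omission", "commission"))
  for (ty in types) expect_s3_class(condition_stats(ep, ty), "condition_stats")
})

test_that("pointwise Z implements the standardized Welch statistic", {
  # identical conditions: Z = 0 everywhere
  a <- make_stats(mean = c(1, -2, 0.5), var = c(1, 2, 3), n = 90)
  z0 <- pointwise_z(a, a)
  expect_true(all(z0$z == 0))
  expect_equal(z0$n_ref, 90L)
  expect_equal(z0$df, 89L)

  # a pointwise t of 2.609 at n_ref = 90 standardizes to Z = 0.275
  se <- sqrt(1 / 90 + 1 / 210)
  b <- make_stats(mean = 0, var = 1, n = 210)
  a2 <- make_stats(mean = 2.609 * se, var = 1, n = 90)
  z <- pointwise_z(a2, b)
  expect_equal(z$z[1, 1], 2.609 / sqrt(90), tolerance = 1e-12)
  expect_equal(round(z$z[1, 1], 3), 0.275)

  # one-sample mode
  a3 <- make_stats(mean = c(0.3), var = c(0.09), n = 100)
  z1 <- pointwise_z(a3)
  expect_equal(z1$mode, "one_sample")
  expect_equal(z1$t[1, 1], 0.3 / sqrt(0.09 / 100))
  expect_equal(z1$z[1, 1], z1$t[1, 1] / sqrt(100))

  # degenerate variance: zero difference gives 0, nonzero gives +/-Inf
  a4 <- make_stats(mean = c(0, 1), var = c(0, 0), n = 50)
  b4 <- make_stats(mean = c(0, 0), var = c(0, 0), n = 50)
  z4 <- pointwise_z(a4, b4)
  expect_equal(z4$z[1, 1], 0)
  expect_true(is.infinite(z4$z[1, 2]) && z4$z[1, 2] > 0)
  expect_true(z4$infinite)
})

test_that("pointwise statistics match a per-point loop oracle", {
  set.seed(55)
  ev <- event_table(onset = seq(1, 60), trial_type = rep(c("Nogo", "Go", "Go"), 20),
                    response_time = ifelse(rep(c(FALSE, TRUE, TRUE), 20), 0.4, NA))
  tc <- matrix(rnorm(2 * 6400), 2)
  ep <- epoch_units(tc, ev, sfreq = 100)
  st_n <- condition_stats(ep, "correct_nogo")
  st_g <- condition_stats(ep, "correct_go")
  z <- pointwise_z(st_n, st_g)
  for (j in c(3, 77, 120)) for (u in 1:2) {
    xn <- ep$values[ep$condition == "correct_nogo", u, j]
    xg <- ep$values[ep$condition == "correct_go", u, j]
    tt <- (mean(xn) - mean(xg)) /
      sqrt(stats::var(xn) / length(xn) + stats::var(xg) / length(xg))
    expect_equal(z$t[u, j], tt, tolerance = 1e-12)
    expect_equal(z$z[u, j], tt / sqrt(min(length(xn), length(xg))),
                 tolerance = 1e-12)
  }
})

test_that("threshold crossings become half-open latency ranges", {
  st <- make_stats(mean = c(1, 1, 1, 1), var = c(1, 1, 1, 1), n = 90)
  z <- make_z(c(0, 0.3, 0.3, 0))
  r <- extract_ranges(z, st, mode = "visual")
  expect_equal(nrow(r), 1L)
  expect_equal(r$t_on, 0.01)
  expect_equal(r$t_off, 0.03)

  z2 <- make_z(c(0.1, 0.2, 0.275, 0.1))
  expect_equal(nrow(extract_ranges(z2, st, mode = "visual")), 0L)
})

test_that("the Nogo dominance rule keeps Nogo-dominant ranges with polarity", {
  z <- make_z(c(0, 0.5, 0.5, 0))
  # Go average larger in magnitude: discard
  st_n <- make_stats(mean = rep(-1, 4), var = rep(1, 4), n = 90)
  st_g <- make_stats(mean = rep(-3, 4), var = rep(1, 4), n = 210)
  expect_equal(nrow(extract_ranges(z, st_n, st_g, mode = "nogo")), 0L)
  # Nogo average larger: keep, polarity from the Nogo sign
  r2 <- extract_ranges(z, stats_nogo = make_stats(rep(-3, 4), rep(1, 4), 90),
                       stats_go = make_stats(rep(-1, 4), rep(1, 4), 210),
                       mode = "nogo")
  expect_equal(nrow(r2), 1L)
  expect_equal(r2$polarity, -1)
  expect_equal(r2$dominant_condition, "Nogo")
})

test_that("ranges reproduce a naive above-threshold scan on random series", {
  set.seed(56)
  for (rep in 1:10) {
    zz <- rnorm(80, sd = 0.2)
    st <- make_stats(mean = rnorm(80), var = rep(1, 80), n = 90)
    z <- make_z(zz)
    r <- extract_ranges(z, st, mode = "visual", threshold = 0.275)
    covered <- logical(80)
    if (nrow(r)) for (k in seq_len(nrow(r))) {
      idx <- which(z$times >= r$t_on[k] - 1e-9 & z$times < r$t_off[k] - 1e-9)
      expect_true(all(abs(zz[idx]) > 0.275))
      covered[idx] <- TRUE
    }
    expect_equal(covered, abs(zz) > 0.275)
  }
})

test_that("analysis windows anchor on the median RT", {
  w <- analysis_windows(0.4)
  expect_equal(w$early, c(0.2, 0.4))
  expect_equal(w$late, c(0.3, 0.7))
  expect_equal(w$visual, c(0.09, 0.14))
})

test_that("window tagging requires strict containment and allows overlap", {
  w <- analysis_windows(0.4)
  ranges <- data.frame(ic = c(1L, 2L, 3L, 4L),
                       t_on = c(0.32, 0.15, 0.45, 0.25),
                       t_off = c(0.38, 0.25, 0.60, 0.35),
                       polarity = 1, dominant_condition = "Nogo",
                       peak_absz = 0.5)
  sel <- select_for_windows(ranges, w, c("early", "late"))
  # [0.32, 0.38) sits inside the early/late overlap [0.3, 0.4]: tagged both
  expect_equal(sort(sel$window[sel$ic == 1]), c("early", "late"))
  # [0.25, 0.35) starts before the late window opens: early only
  expect_equal(sel$window[sel$ic == 4], "early")
  # [0.15, 0.25) starts before 0.200: dropped entirely
  expect_false(2L %in% sel$ic)
  # [0.45, 0.60) fits only the late window
  expect_equal(sel$window[sel$ic == 3], "late")
})

test_that("selection is invariant to IC sign flips up to the polarity tag", {
  cfg <- small_cfg(57)
  ev <- gen_paradigm(cfg)
  eeg <- gen_eeg(ev, cfg)
  dec <- fit_small(eeg$recording)
  act <- ic_activations(dec, eeg$recording)
  ep1 <- suppressMessages(epoch_units(act, ev, sfreq = 100))
  act2 <- act; act2[2, ] <- -act2[2, ]
  ep2 <- suppressMessages(epoch_units(act2, ev, sfreq = 100))
  s1 <- select_ics(ep1, "nogo")
  s2 <- select_ics(ep2, "nogo")
  expect_equal(s1$selection[, c("ic", "t_on", "t_off", "window")],
               s2$selection[, c("ic", "t_on", "t_off", "window")])
  flip <- s1$selection$ic == 2L
  expect_equal(s2$selection$polarity[flip], -s1$selection$polarity[flip])
  expect_equal(s2$selection$polarity[!flip], s1$selection$polarity[!flip])
  for (w in intersect(unique(s1$selection$window), c("early", "late"))) {
    a1 <- single_trial_amplitudes(ep1, s1$selection, w)
    a2 <- single_trial_amplitudes(ep2, s2$selection, w)
    expect_equal(a1$values, a2$values, tolerance = 1e-12)
  }
})

test_that("artifact ICs are excluded from the candidate set", {
  cfg <- small_cfg(58)
  ev <- gen_paradigm(cfg)
  eeg <- gen_eeg(ev, cfg)
  dec <- fit_small(eeg$recording)
  act <- ic_activations(dec, eeg$recording)
  ep <- suppressMessages(epoch_units(act, ev, sfreq = 100))
  s_all <- select_ics(ep, "nogo")
  if (nrow(s_all$selection)) {
    drop_ic <- s_all$selection$ic[1]
    s_ex <- select_ics(ep, "nogo", exclude = drop_ic)
    expect_false(drop_ic %in% s_ex$selection$ic)
  }
  expect_error(select_ics(ep, "nogo", z_threshold = -1), "positive")
})

test_that("visual mode pools conditions and selects in 90-140 ms", {
  cfg <- small_cfg(59)
  ev <- gen_paradigm(cfg)
  eeg <- gen_eeg(ev, cfg)
  dec <- fit_small(eeg$recording)
  act <- ic_activations(dec, eeg$recording)
  ep <- suppressMessages(epoch_units(act, ev, sfreq = 100))
  s <- select_ics(ep, "visual")
  expect_true(nrow(s$selection) >= 1L)
  expect_true(all(s$selection$window == "visual"))
  expect_true(all(s$selection$t_on >= 0.09 - 1e-9))
  expect_true(all(s$selection$t_off <= 0.14 + 1e-9))
  # the selected IC should be the planted visual source
  vis_ic <- which.max(abs(stats::cor(t(act), eeg$truth$sources["visual", ])))
  expect_true(vis_ic %in% s$selection$ic)
})
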