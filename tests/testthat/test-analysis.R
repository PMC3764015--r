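test_that("sleep/wake scoring merges bouts and breaks ties as sleep", {
  thr <- 1
  # constant series above threshold: one wake bout spanning the record
  b <- score_sleep_wake(rep(5, 100), thr, sampling_interval_s = 60)
  expect_equal(nrow(b), 1)
  expect_equal(b$state, "wake")
  expect_equal(b$end_s - b$start_s, 6000)
  # exactly at threshold everywhere: scored asleep (strict inequality)
  b2 <- score_sleep_wake(rep(thr, 50), thr, sampling_interval_s = 60)
  expect_equal(b2$state, "sleep")
  # square wave with 4-h period: alternating 2-h bouts
  qm <- rep(rep(c(5, 0), each = 120), 6)  # 1-min sampling
  b3 <- score_sleep_wake(qm, thr, sampling_interval_s = 60)
  expect_true(all(abs(b3$end_s - b3$start_s - 7200) < 1))
  expect_true(all(b3$state[seq(1, nrow(b3), 2)] == "wake"))
  expect_error(score_sleep_wake(numeric(0), thr, sampling_interval_s = 60),
               "empty")
})

test_that("scoring conserves time: wake% + sleep% = 100", {
  set.seed(1)
  qm <- runif(5000, 0, 3)
  b <- score_sleep_wake(qm, 1, sampling_interval_s = 30)
  dur <- b$end_s - b$start_s
  wake_pct <- 100 * sum(dur[b$state == "wake"]) / sum(dur)
  expect_equal(wake_pct + total_sleep_fraction(b), 100)
})

test_that("activity windows average as specified in both modes", {
  # constant input: every window mean equals the constant
  tr <- activity_trace(rep(2.5, 288), width_s = 600,
                       sampling_interval_s = 300)
  expect_true(all(abs(tr$activity - 2.5) < 1e-12))
  # 24-h record, 10-min non-overlapping windows: 144 windows
  qm <- rnorm(2880, 2)  # 30-s sampling
  tr2 <- activity_trace(qm, 600, "non-overlapping",
                        sampling_interval_s = 30)
  expect_equal(nrow(tr2), 144)
  # sliding impulse response: one high sample spreads over width/stride
  # windows with value h/w (direct convolution check)
  qm3 <- rep(0, 200)
  qm3[100] <- 7
  tr3 <- activity_trace(qm3, 300, "sliding", sampling_interval_s = 30)
  expect_equal(sum(tr3$activity > 0), 10)
  expect_equal(max(tr3$activity), 7 / 10)
  expect_error(activity_trace(qm3, 10, sampling_interval_s = 30), "shorter")
})

test_that("raster folds, double-plots, and responds monotonically to threshold", {
  qm <- rep(5, 2 * 2880)  # 2 days at 30 s
  tr <- activity_trace(qm, 600, "sliding", sampling_interval_s = 30)
  r <- raster(tr, double_plot = FALSE, high_threshold = 1)
  expect_true(all(r))
  r2 <- raster(tr, double_plot = TRUE, high_threshold = 1)
  expect_equal(ncol(r2), 2 * ncol(r))
  # bar coverage decreases monotonically as the threshold rises
  set.seed(2)
  qm3 <- pmax(0, rnorm(3 * 2880, 2, 2))
  tr3 <- activity_trace(qm3, 600, "sliding", sampling_interval_s = 30)
  cov <- vapply(c(1, 2, 3),
                function(th) mean(raster(tr3, high_threshold = th)), 1)
  expect_true(all(diff(cov) < 0))
  expect_error(raster(tr[1:100, ], high_threshold = 1), "fold period")
})

test_that("circadian-binned wake percentage folds and aligns correctly", {
  # all-wake record: 100% in every bin
  b <- score_sleep_wake(rep(5, 4 * 1440), 1, sampling_interval_s = 60)
  prof <- percent_wake_by_circadian_bin(b, period_h = 24)
  expect_true(all(prof$pct_wake == 100))
  # periodic monophasic record: profile independent of record length
  qm2 <- synthetic_monophasic_qm(24, 2)
  qm4 <- synthetic_monophasic_qm(24, 4)
  p2 <- percent_wake_by_circadian_bin(
    score_sleep_wake(qm2, 1, sampling_interval_s = 60), 24)
  p4 <- percent_wake_by_circadian_bin(
    score_sleep_wake(qm4, 1, sampling_interval_s = 60), 24)
  expect_equal(p2$pct_wake, p4$pct_wake, tolerance = 0.02)
  # phase zero: first bin above 50% after a bin at or below 50%
  expect_gt(p4$pct_wake[1], 50)
  expect_lte(p4$pct_wake[24], 50)
  expect_error(percent_wake_by_circadian_bin(
    score_sleep_wake(rep(5, 100), 1, sampling_interval_s = 60), 24),
    "shorter")
})

test_that("amplitude spectrum finds pure and mixed sinusoids and normalizes", {
  dt <- 60
  t <- seq(0, 10 * 86400 - dt, by = dt)
  y <- sin(2 * pi * t / (6 * 3600))
  sp <- amplitude_spectrum(y, band = c(2, 30), sampling_interval_s = dt)
  expect_equal(peak_period(sp), 6, tolerance = 0.05)
  # area normalization: trapezoidal integral over the band is 1
  area <- sum(diff(sp$period_h) *
                (head(sp$amplitude, -1) + tail(sp$amplitude, -1)) / 2)
  expect_equal(area, 1, tolerance = 1e-9)
  # two sinusoids: two peaks with the input amplitude ratio
  y2 <- sin(2 * pi * t / (8 * 3600)) + 0.4 * sin(2 * pi * t / (3 * 3600))
  sp2 <- amplitude_spectrum(y2, band = c(2, 30), sampling_interval_s = dt)
  a8 <- max(sp2$amplitude[abs(sp2$period_h - 8) < 0.5])
  a3 <- max(sp2$amplitude[abs(sp2$period_h - 3) < 0.2])
  expect_equal(a3 / a8, 0.4, tolerance = 0.05)
  expect_error(amplitude_spectrum(y[1:100], band = c(2, 30),
                                  sampling_interval_s = dt), "twice")
})

test_that("spectrum normalization holds for arbitrary signals (property)", {
  set.seed(3)
  for (k in 1:5) {
    y <- rnorm(2000) + k * sin(2 * pi * seq_len(2000) / sample(50:500, 1))
    sp <- amplitude_spectrum(y, band = c(2, 20), sampling_interval_s = 300)
    area <- sum(diff(sp$period_h) *
                  (head(sp$amplitude, -1) + tail(sp$amplitude, -1)) / 2)
    expect_equal(area, 1, tolerance = 1e-9)
  }
})

test_that("peak period is invariant to amplitude scaling", {
  set.seed(4)
  y <- sin(2 * pi * seq_len(5000) / 120) + 0.3 * rnorm(5000)
  s1 <- amplitude_spectrum(y, band = c(2, 20), sampling_interval_s = 300)
  s2 <- amplitude_spectrum(50 * y, band = c(2, 20),
                           sampling_interval_s = 300)
  expect_equal(peak_period(s1), peak_period(s2))
  expect_error(peak_period(s1, band = c(100, 200)), "empty band")
})

test_that("free-running period recovers constructed onset drifts", {
  # one main sleep bout per cycle at exactly 25 h: slope gives 25.0
  b25 <- score_sleep_wake(synthetic_monophasic_qm(25, 15), 1,
                          sampling_interval_s = 60)
  expect_equal(free_running_period(b25), 25, tolerance = 0.02)
  # zero drift: 24.0
  b24 <- score_sleep_wake(synthetic_monophasic_qm(24, 15), 1,
                          sampling_interval_s = 60)
  expect_equal(free_running_period(b24), 24, tolerance = 0.02)
  expect_error(free_running_period(
    score_sleep_wake(rep(5, 1000), 1, sampling_interval_s = 60)),
    "too few")
})

test_that("waveform modality counts peaks with merging and prominence", {
  dt <- 600
  t <- seq(0, 20 * 86400 - dt, by = dt)
  mk_trace <- function(y) activity_trace(y, 600, "non-overlapping",
                                         sampling_interval_s = dt)
  # unimodal daily waveform
  uni <- waveform_modality(mk_trace(2 + sin(2 * pi * t / 86400)))
  expect_equal(uni$n_peaks, 1)
  # bimodal: two humps per day
  bi <- waveform_modality(mk_trace(2 + sin(2 * pi * t / 43200)))
  expect_equal(bi$n_peaks, 2)
  # twin peaks closer than the merge distance count once
  h <- ((t / 3600) %% 24)
  twin <- exp(-(h - 11.5)^2 / 0.5) + exp(-(h - 12.5)^2 / 0.5)
  expect_equal(waveform_modality(mk_trace(twin), merge_h = 2)$n_peaks, 1)
})
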