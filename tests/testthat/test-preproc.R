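# analytic magnitude response of the zero-phase band-pass realization:
# |H(e^{iw})|^2 because the filter runs forward and backward
filtfilt_gain <- function(f, fs, lo = 8, hi = 32, order = 4) {
  filt <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  w <- 2 * pi * f / fs
  z <- exp(-1i * w * (seq_along(filt$b) - 1))
  Mod(sum(filt$b * z) / sum(filt$a * z))^2
}

steady_amp <- function(y, fs) {
  mid <- y[(fs):(length(y) - fs)]        # drop 1 s transients at both ends
  sqrt(2 * mean(mid^2))
}

test_that("band-pass rejects DC and the 50 Hz band, passes 20 Hz", {
  fs <- 250
  t <- seq(0, 12, by = 1 / fs)
  dc <- bandpass_filter(rep(1, length(t)), fs = fs)
  expect_lt(max(abs(dc[(fs):(length(dc) - fs)])), 1e-6)

  y20 <- bandpass_filter(sin(2 * pi * 20 * t), fs = fs)
  a20 <- steady_amp(y20, fs)
  expect_equal(a20, filtfilt_gain(20, fs), tolerance = 1e-3)
  expect_lt(abs(a20 - 1), 0.05)

  y50 <- bandpass_filter(sin(2 * pi * 50 * t), fs = fs)
  a50 <- steady_amp(y50, fs)
  expect_equal(a50, filtfilt_gain(50, fs), tolerance = 1e-2)
  expect_lt(a50, 0.05)
})

test_that("filtering is linear and validates its band", {
  set.seed(7)
  x <- rnorm(2000)
  y1 <- bandpass_filter(3.7 * x, fs = 250)
  y2 <- 3.7 * bandpass_filter(x, fs = 250)
  expect_lt(max(abs(y1 - y2)) / max(abs(y2)), 1e-9)
  expect_error(bandpass_filter(x, lo = 8, hi = 130, fs = 250), "invalid band")
  expect_error(bandpass_filter(x, lo = 0, hi = 32, fs = 250), "invalid band")
})

test_that("baseline correction removes per-channel offsets and is idempotent", {
  fs <- 250
  t <- seq(-0.5, by = 1 / fs, length.out = 375)
  n <- length(t)
  data <- array(0, dim = c(1, 2, n))
  data[1, 1, ] <- sin(2 * pi * 5 * t) + 3
  data[1, 2, ] <- cos(2 * pi * 5 * t) - 7
  ep <- eeg_epochs(data, labels = 0, fs = fs, t_start = -0.5)
  out <- baseline_correct(ep)
  i <- which(t >= -0.2 & t < 0)   # half-open baseline window convention
  expect_equal(mean(out$data[1, 1, i]), 0, tolerance = 1e-10)
  expect_equal(mean(out$data[1, 2, i]), 0, tolerance = 1e-10)
  twice <- baseline_correct(out)
  expect_equal(twice$data, out$data, tolerance = 1e-12)

  zero <- eeg_epochs(array(0, dim = c(1, 2, n)), 0, fs, t_start = -0.5)
  expect_equal(baseline_correct(zero)$data, zero$data)

  late <- eeg_epochs(data, 0, fs, t_start = 0.5)
  expect_error(baseline_correct(late), "outside the epoch")
})

test_that("window segmentation produces the documented counts and starts", {
  fs <- 250
  trial <- matrix(rnorm(2 * 5 * fs), nrow = 2)   # 5 s trial starting at 0 s
  w <- window_segment(trial, fs, win_s = 2, stride_s = 0.04,
                      t_start_s = 1, t_end_s = 4)
  expect_length(w, 26)
  expect_equal(attr(w, "starts"), 1 + 0.04 * (0:25))
  expect_equal(ncol(w[[1]]), 500)

  expect_length(window_segment(trial, fs, win_s = 3, stride_s = 0.5,
                               t_start_s = 1, t_end_s = 4), 1)
  expect_length(window_segment(trial, fs, win_s = 2, stride_s = 0.5,
                               t_start_s = 1, t_end_s = 3.5), 2)
  expect_error(window_segment(trial, fs, win_s = 0), "must be > 0")
  expect_error(window_segment(trial, fs, win_s = 2, t_start_s = 1,
                              t_end_s = 2.5), "shorter than the window")
})

test_that("epoch extraction and windowing agree with trial bookkeeping", {
  set.seed(2)
  fs <- 250
  samples <- matrix(rnorm(3 * 10 * fs), nrow = 3)
  events <- data.frame(onset = c(500, 1200), label = c(0, 2))
  rec <- eeg_recording(samples, c("C3", "Cz", "C4"), fs, events)
  ep <- extract_epochs(rec, t_before = 0.5, t_after = 4.3)
  expect_equal(dim(ep$data), c(2, 3, 1200))
  expect_equal(ep$labels, c(0L, 2L))
  expect_equal(ep$data[1, , 1], samples[, 500 - 125])

  wins <- epochs_to_windows(ep)
  expect_equal(dim(wins$data)[1], 2 * 26)
  expect_equal(unique(wins$trial_id), 1:2)
  expect_equal(wins$labels, rep(c(0L, 2L), each = 26))
})
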