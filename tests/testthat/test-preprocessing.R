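make_rec <- function(x, fs = 2200) sipemg:::new_recording(x, fs, 1L, 1L, "right")

test_that("band-pass response passes 50 Hz and rejects 1000 Hz", {
  fs <- 2200
  cfg <- preprocess_config()
  # designed-response oracle: squared Butterworth magnitude (filtfilt)
  bt <- signal::butter(cfg$filter_order, c(10, 400) / (fs / 2), type = "pass")
  H <- function(f_hz) {
    z <- exp(-1i * 2 * pi * f_hz / fs)
    k <- seq_along(bt$b) - 1
    Mod(sum(bt$b * z^k) / sum(bt$a * z^k))^2  # filtfilt squares |H|
  }
  expect_gt(H(50), 0.95)
  expect_lt(H(1000), 0.01)

  t <- (0:(8 * fs - 1)) / fs
  y50 <- bandpass_filter(make_rec(sin(2 * pi * 50 * t)), cfg)$samples
  mid <- (2 * fs):(6 * fs)
  amp <- sqrt(2 * mean(y50[mid]^2))
  expect_gt(amp, 0.95); expect_lt(amp, 1.05)

  y1k <- bandpass_filter(make_rec(sin(2 * pi * 1000 * t)), cfg)$samples
  expect_lt(sqrt(mean(y1k[mid]^2)), 0.1 * sqrt(0.5))

  expect_equal(bandpass_filter(make_rec(numeric(1000)))$samples, numeric(1000))
  expect_error(bandpass_filter(make_rec(rnorm(100), fs = 500)), "Nyquist")
})

test_that("envelope is rectification-symmetric and tracks a DC level", {
  fs <- 2200
  x <- rnorm(4 * fs)
  e1 <- emg_envelope(make_rec(x))$samples
  e2 <- emg_envelope(make_rec(-x))$samples
  expect_identical(e1, e2)
  expect_true(all(e1 >= 0))

  const <- emg_envelope(make_rec(rep(0.7, 6 * fs)))$samples
  mid <- (2 * fs):(4 * fs)
  expect_true(all(abs(const[mid] - 0.7) < 0.01))
})

test_that("envelope argmax matches the true modulation peak of an AM burst", {
  fs <- 2200
  set.seed(9)
  n <- 6 * fs
  env_true <- numeric(n)
  peak_at <- 3 * fs
  m <- fs  # 1-s Hann bump centred at 3 s
  idx <- (peak_at - m / 2):(peak_at + m / 2 - 1)
  env_true[idx] <- sipemg:::hann_bump(m)
  x <- env_true * rnorm(n) + rnorm(n, 0, 0.02)
  e <- emg_envelope(make_rec(x))$samples
  expect_lt(abs(which.max(e) - peak_at) / fs, 0.05)
})

test_that("burst windows have exact length, centred peaks, and flagged padding", {
  fs <- 2200
  set.seed(10)
  n <- 8 * fs
  x <- rnorm(n, 0, 0.01)
  m <- fs
  idx <- (3 * fs - m / 2):(3 * fs + m / 2 - 1)
  x[idx] <- x[idx] + sipemg:::hann_bump(m) * rnorm(m)
  rec <- make_rec(x)
  ann <- data.frame(time_s = 3.0, label = "drink", volume_ml = 10,
                    event_index = 1L)
  w <- extract_bursts(rec, ann)[[1]]
  expect_equal(length(w$samples), 4400L)
  expect_equal(w$peak_index, 2201L)
  expect_lt(abs(w$peak_time_s - 3.0), 0.05)
  expect_false(w$padded)
  # peak at ~3.0 s -> window covers [2.0 s, 4.0 s)
  expect_lt(abs(w$start_time_s - 2.0), 0.06)

  # halving the window halves the sample count, nothing else
  w05 <- extract_bursts(rec, ann, preprocess_config(window_s = 0.5))[[1]]
  expect_equal(length(w05$samples), 1100L)
  expect_equal(w05$peak_time_s, w$peak_time_s)

  # event near the recording edge: padded but exact length
  x2 <- rnorm(n, 0, 0.01)
  ii <- round(0.15 * fs) + (-150:150)
  x2[ii] <- x2[ii] + 5 * sipemg:::hann_bump(301) * rnorm(301)
  ann_edge <- data.frame(time_s = 0.15, label = "cough", volume_ml = NA,
                         event_index = 2L)
  we <- extract_bursts(make_rec(x2), ann_edge)[[1]]
  expect_equal(length(we$samples), 4400L)
  expect_true(we$padded)
  expect_lt(we$peak_time_s, 1)

  # annotation outside the recording: skipped with an error record
  ann_bad <- data.frame(time_s = c(3.0, 99), label = c("drink", "talk"),
                        volume_ml = c(10, NA), event_index = 1:2)
  res <- extract_bursts(rec, ann_bad)
  expect_equal(length(res), 1L)
  expect_equal(attr(res, "skipped")$event_index, 2L)

  # determinism
  res2 <- extract_bursts(rec, ann)
  expect_identical(res2[[1]]$samples, w$samples)
})

test_that("detected peaks match generator truth for >= 95% of drinking events", {
  st <- default_cell_study()
  w <- default_cell_windows()
  ann <- st$annotations
  err <- vapply(w, function(x) {
    a <- ann[ann$event_index == x$event_index, ]
    abs(x$peak_time_s - a$time_s)
  }, 0)
  lab <- vapply(w, `[[`, "", "label")
  expect_gte(mean(err[lab == "drink"] <= 0.05), 0.95)
})
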