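# Pitch tracking, intensity contours, calibration, frame targets.

test_that("tracker recovers a constant 120 Hz pulse train within 0.1 ST", {
  tr <- make_pulse_train(120, duration_s = 1, snr_db = 30)
  f0 <- extract_f0(tr)
  v <- f0$values[!is.na(f0$values)]
  expect_gt(length(v), 10)
  med <- stats::median(v)
  expect_lt(abs(hz_to_semitones(med, 120)), 0.1)
})

test_that("autocorrelation peak of the source sits at the configured period", {
  # independent oracle: peak-picking on the full autocorrelation
  tr <- make_pulse_train(120, duration_s = 1, snr_db = 60)
  x <- tr$samples
  r <- acf(x, lag.max = 600, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  search <- 200:500                      # lag window around fs/120 = 367.5
  peak_lag <- search[which.max(r[search + 1])]
  expect_lt(abs(peak_lag - 44100 / 120), 2)
})

test_that("silence and too-short input behave as documented", {
  silent <- signal_track(numeric(44100), 44100)
  f0 <- extract_f0(silent)
  expect_equal(sum(!is.na(f0$values)), 0L)
  short <- signal_track(numeric(400), 44100)
  expect_length(extract_f0(short)$values, 0L)
  expect_error(extract_f0(signal_track(rnorm(5000), 1000)), "rate")
})

test_that("a pure sine is tracked at its frequency, not an octave", {
  t <- (0:(44100 - 1)) / 44100
  s <- signal_track(sin(2 * pi * 200 * t), 44100)
  f0 <- extract_f0(s)
  v <- f0$values[!is.na(f0$values)]
  expect_gt(length(v), 10)
  expect_lt(abs(hz_to_semitones(stats::median(v), 200)), 0.1)
  # no value near 100 or 400 Hz anywhere on the path
  expect_false(any(abs(hz_to_semitones(v, 100)) < 1))
  expect_false(any(abs(hz_to_semitones(v, 400)) < 1))
})

test_that("glide halves the period across the sweep (brute-force acf lag)", {
  # the resonator dominates raw zero crossings, so the brute-force oracle
  # peak-picks the autocorrelation period in the first and last 150 ms
  step <- 0.005
  times <- seq(0, 1 - step, by = step)
  cont <- contour(times, 100 + 100 * times / max(times), "Hz")
  src <- glottal_source(cont, 44100, 3)
  period_of <- function(x, lo, hi) {
    r <- acf(x, lag.max = hi, plot = FALSE, demean = TRUE)$acf[, 1, 1]
    (lo:hi)[which.max(r[(lo:hi) + 1])]
  }
  first <- src$samples[1:6615]
  last <- src$samples[(length(src$samples) - 6614):length(src$samples)]
  p1 <- period_of(first, 300, 600)    # ~100-147 Hz admissible
  p2 <- period_of(last, 150, 300)     # ~147-294 Hz admissible
  # window-mean frequencies: 107.5 Hz (first 150 ms), 192.5 Hz (last)
  expect_equal(44100 / p1, 107.5, tolerance = 0.05)
  expect_equal(44100 / p2, 192.5, tolerance = 0.05)
  # the instantaneous rate roughly doubles end to end
  expect_gt(p1 / p2, 1.6)
})

test_that("intensity obeys 20 log10 amplitude scaling", {
  t <- (0:(2 * 44100 - 1)) / 44100
  s1 <- signal_track(0.1 * sin(2 * pi * 220 * t), 44100)
  s2 <- signal_track(0.2 * sin(2 * pi * 220 * t), 44100)
  i1 <- extract_intensity(s1); i2 <- extract_intensity(s2)
  mid <- abs(i1$times - 1) < 0.4
  expect_equal(stats::median(i2$values[mid] - i1$values[mid]), 6.02,
               tolerance = 0.05)
  # plateau is flat
  expect_lt(stats::sd(i1$values[mid]), 0.1)
  # gain g shifts uniformly by 20 log10 g
  g <- 3.7
  s3 <- signal_track(g * s1$samples, 44100)
  i3 <- extract_intensity(s3)
  expect_lt(max(abs((i3$values - i1$values) - 20 * log10(g))), 0.05)
})

test_that("full-scale sine sits near 91 dB and silence at the floor", {
  t <- (0:(44100 - 1)) / 44100
  s <- signal_track(sin(2 * pi * 300 * t), 44100)
  i <- extract_intensity(s)
  expect_equal(stats::median(i$values), 91, tolerance = 0.2)
  z <- extract_intensity(signal_track(numeric(22050), 44100))
  expect_true(all(is.finite(z$values)))
  expect_true(all(z$values <= -190))
})

test_that("an amplitude step produces a 20 dB rise over ~one window", {
  t <- (0:(2 * 44100 - 1)) / 44100
  amp <- ifelse(t < 1, 0.05, 0.5)
  s <- signal_track(amp * sin(2 * pi * 220 * t), 44100)
  i <- extract_intensity(s)
  lo <- stats::median(i$values[i$times > 0.4 & i$times < 0.8])
  hi <- stats::median(i$values[i$times > 1.2 & i$times < 1.6])
  expect_equal(hi - lo, 20, tolerance = 0.1)
  wdur <- 3.2 / 65
  in_transition <- i$values > lo + 1 & i$values < hi - 1
  trans_width <- diff(range(i$times[in_transition]))
  expect_lt(trans_width, 1.5 * wdur)
})

test_that("SPL calibration shifts additively and round-trips", {
  cont <- contour(seq(0, 1, by = 0.01), rnorm(101, 60), "dB")
  cal0 <- calibration_info(70, 70)
  expect_equal(calibrate_spl(cont, cal0)$values, cont$values)
  cal <- calibration_info(82, 70)
  up <- calibrate_spl(cont, cal)
  expect_equal(up$values - cont$values, rep(12, 101))
  expect_equal(up$unit, "dB SPL")
  back <- calibrate_spl(up, cal, inverse = TRUE)
  expect_equal(back$values, cont$values, tolerance = 1e-12)
  expect_equal(back$unit, "dB")
  expect_error(calibrate_spl(up, cal), "expected a contour in dB")
})

test_that("frame_targets arithmetic, constants and coverage", {
  times <- seq(0, 0.995, by = 0.005)
  cont <- contour(times, rep(7, length(times)), "Hz")
  ft <- frame_targets(cont, 0.040, 0.020)
  expect_length(ft$values, 49L)                 # floor((1000-40)/20) + 1
  expect_true(all(ft$values == 7))
  expect_equal(ft$times[1], 0.020)              # centre of [0, 40 ms)
  expect_equal(diff(ft$times)[1], 0.020)
  # half-defined contour: frames over the undefined half are dropped
  half <- contour(times, c(rep(3, 100), rep(NA, 100)), "Hz")
  fh <- frame_targets(half, 0.040, 0.020, min_coverage = 0.5)
  expect_true(all(is.na(fh$values[fh$times > 0.53])))
  expect_true(all(!is.na(fh$values[fh$times < 0.48])))
  expect_length(frame_targets(contour(numeric(0), numeric(0), "Hz"),
                              0.04, 0.02)$values, 0L)
})

test_that("contour grids conform to the configured step without drift", {
  tr <- make_pulse_train(150, duration_s = 4, seed = 9)
  p <- pitch_params()
  f0 <- extract_f0(tr, p)
  steps <- diff(f0$times)
  expect_lt(max(abs(steps - p$time_step)), 1e-9)
  i <- extract_intensity(tr)
  expect_lt(max(abs(diff(i$times) - 0.8 / 65)), 1e-9)
})
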