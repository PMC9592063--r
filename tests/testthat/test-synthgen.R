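# Synthetic sessions: determinism, source properties, sEMG realism,
# prosody-EMG coupling.

test_that("identical configs reproduce bit-identical sessions", {
  s1 <- generate_session(synth_config(5, task_type = "tone", duration_s = 2))
  s2 <- generate_session(synth_config(5, task_type = "tone", duration_s = 2))
  expect_identical(s1$audio$samples, s2$audio$samples)
  expect_identical(lapply(s1$emg, `[[`, "samples"),
                   lapply(s2$emg, `[[`, "samples"))
  expect_identical(s1$truth_f0$values, s2$truth_f0$values)
  s3 <- generate_session(synth_config(6, task_type = "tone", duration_s = 2))
  expect_false(identical(s1$audio$samples, s3$audio$samples))
})

test_that("glottal source: silence case and input validation", {
  times <- seq(0, 0.995, by = 0.005)
  silent <- contour(times, rep(NA_real_, length(times)), "Hz")
  out <- glottal_source(silent, 44100, 1)
  expect_lt(max(abs(out$samples)), 1e-9)
  bad <- contour(times, rep(10, length(times)), "Hz")
  expect_error(glottal_source(bad, 44100, 1), "20, 1000")
})

test_that("emg_from_activation: RMS monotonicity and band limits", {
  times <- seq(0, 9.995, by = 0.005)
  act_c <- contour(times, rep(1, length(times)), "a.u.")
  act_2c <- contour(times, rep(2, length(times)), "a.u.")
  e1 <- emg_from_activation(act_c, 2222, noise_floor = 0, seed = 3)
  e2 <- emg_from_activation(act_2c, 2222, noise_floor = 0, seed = 3)
  rms <- function(x) sqrt(mean(x^2))
  expect_equal(rms(e2$samples) / rms(e1$samples), 2, tolerance = 0.05)
  zero <- emg_from_activation(contour(times, numeric(length(times)), "a.u."),
                              2222, noise_floor = 0, seed = 3)
  expect_equal(rms(zero$samples), 0)
  neg <- contour(times, rep(-1, length(times)), "a.u.")
  expect_error(emg_from_activation(neg, 2222, seed = 3), ">= 0")
  # >95% of power inside 15-455 Hz (Welch periodogram integration)
  x <- e1$samples
  n <- length(x)
  spec <- Mod(fft(x))^2 / n
  f <- (seq_len(n) - 1) / n * 2222
  half <- f <= 1111
  inband <- half & f >= 15 & f <= 455
  expect_gt(sum(spec[inband]) / sum(spec[half]), 0.95)
})

test_that("tone sessions are stationary; disjoint pitches separate", {
  s <- generate_session(synth_config(9, task_type = "tone", duration_s = 4))
  x <- s$emg[[1]]$samples
  fs <- s$emg[[1]]$rate
  # voiced interior windows only (edges are unvoiced)
  w1 <- x[round(0.5 * fs):round(1.5 * fs)]
  w2 <- x[round(2.0 * fs):round(3.0 * fs)]
  rms <- function(v) sqrt(mean(v^2))
  expect_lt(abs(rms(w1) / rms(w2) - 1), 0.10)

  # two sessions with disjoint constant f0, same gains: the f0-coupled
  # channel envelopes separate
  base <- synth_config(10, task_type = "tone", duration_s = 3)
  mk <- function(f0) {
    traj <- list(f0 = function(t) rep(f0, length(t)),
                 intensity = function(t) rep(65, length(t)),
                 voicing = function(t) rep(TRUE, length(t)))
    cfg <- synth_config(10, task_type = "tone", duration_s = 3,
                        trajectories = traj,
                        coupling_gains = base$coupling_gains)
    generate_session(cfg)
  }
  lo <- mk(100); hi <- mk(200)
  g <- base$coupling_gains[, "f0_st"]
  ch <- which.max(abs(g))
  rlo <- sqrt(mean(lo$emg[[ch]]$samples^2))
  rhi <- sqrt(mean(hi$emg[[ch]]$samples^2))
  expect_gt(abs(log(rhi / rlo)), 0.2)
})

test_that("voicing bookkeeping matches the configured trajectory", {
  s <- phrase_session()
  cfgv <- s$config$trajectories$voicing(s$truth_f0$times)
  expect_lt(abs(voiced_fraction(s$truth_f0) - mean(cfgv)), 0.02)
  # truth_f0 is undefined exactly where voicing is off
  expect_identical(is.na(s$truth_f0$values), !cfgv)
})

test_that("channel RMS tracks truth intensity (coupling sanity)", {
  s <- cached("phrase60",
              generate_session(synth_config(19, task_type = "phrase",
                                            duration_s = 60)))
  fs <- s$emg[[1]]$rate
  win <- round(0.1 * fs)
  nw <- floor(length(s$emg[[1]]$samples) / win)
  rms <- vapply(s$emg, function(tr)
    sqrt(colMeans(matrix(tr$samples[seq_len(nw * win)], win)^2)),
    numeric(nw))
  tmid <- (seq_len(nw) - 0.5) * win / fs
  ti <- contour_at(s$truth_intensity, tmid)
  # linear regression of intensity on the 8 channel envelopes: the multiple
  # correlation is the floor that makes end-to-end recovery testable
  fit <- lm.fit(cbind(1, rms), ti)
  mult_r <- sqrt(1 - sum(fit$residuals^2) / sum((ti - mean(ti))^2))
  expect_gte(mult_r, 0.7)
  # and most individual channels track intensity on their own
  single <- apply(rms, 2, cor, y = ti)
  expect_gte(stats::median(single), 0.6)
})

test_that("audio and EMG tracks span the same duration", {
  s <- generate_session(synth_config(13, task_type = "vcv"))
  for (tr in s$emg)
    expect_lt(abs(track_duration(tr) - track_duration(s$audio)), 1 / tr$rate)
})

test_that("sessions round-trip through disk", {
  s <- generate_session(synth_config(14, task_type = "legato",
                                     duration_s = 2))
  d <- tempfile()
  write_session(s, d)
  s2 <- read_session(d)
  expect_equal(s2$audio$samples, s$audio$samples, tolerance = 1e-6)
  expect_equal(s2$emg[[3]]$samples, s$emg[[3]]$samples, tolerance = 1e-6)
  expect_equal(s2$truth_f0$values, s$truth_f0$values, tolerance = 1e-7)
  expect_identical(s2$task_label, s$task_label)
  expect_equal(s2$calibration_offset_db, s$calibration_offset_db)
  unlink(d, recursive = TRUE)
})

test_that("WAV IO round-trips both encodings", {
  with_seed_local(15, x <- runif(5000, -0.9, 0.9))
  tr <- signal_track(x, 44100)
  f <- tempfile(fileext = ".wav")
  write_wav(tr, f, bits = 16L)
  r16 <- read_wav(f)
  expect_equal(r16$samples, x, tolerance = 1e-4)
  expect_equal(r16$rate, 44100)
  write_wav(tr, f, bits = 32L)
  r32 <- read_wav(f)
  expect_equal(r32$samples, x, tolerance = 1e-7)
  unlink(f)
})
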