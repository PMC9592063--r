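# The per-frame feature battery: framing arithmetic, family-by-family
# correctness and equivariances, pairwise families, assembly.

test_that("framing arithmetic matches the 40/20 and 150/30 specs", {
  tr <- signal_track(rnorm(2222), 2222)
  f1 <- frame_signal(tr, frame_spec(0.040, 0.020))
  expect_equal(dim(f1$frames), c(89L, 49L))
  f2 <- frame_signal(tr, frame_spec(0.150, 0.030))
  expect_equal(dim(f2$frames), c(333L, 29L))
  # frames tile the signal: frame k starts at (k-1) * step
  expect_equal(f1$times, (0:48) * 0.020, tolerance = 1e-6)
  expect_equal(f1$frames[, 2], tr$samples[45:133])
  short <- signal_track(rnorm(50), 2222)
  expect_length(frame_signal(short, frame_spec(0.040, 0.020))$times, 0L)
})

test_that("time-domain features: constants, oracle ZC count, homogeneity", {
  const <- time_domain_features(rep(2.5, 89))
  expect_equal(unname(const[c("wl", "zc", "ssc", "var")]), c(0, 0, 0, 0))
  expect_equal(unname(const["rms"]), 2.5)
  expect_equal(unname(const["mav"]), 2.5)

  # 50 Hz sine over 40 ms: brute-force oracle count of sign changes
  t <- (0:88) / 2222
  s <- sin(2 * pi * 50 * t + 0.3)
  oracle_zc <- sum(sign(s[-1]) * sign(s[-length(s)]) < 0)
  got <- time_domain_features(s, eps_factor = 1e-9)
  expect_equal(unname(got["zc"]), oracle_zc)

  with_seed_local(12, fr <- rnorm(89))
  g <- 3.3
  a <- time_domain_features(fr); b <- time_domain_features(g * fr)
  expect_equal(unname(b[c("mav", "rms", "wl")]),
               unname(g * a[c("mav", "rms", "wl")]), tolerance = 1e-12)
  expect_equal(unname(b["var"]), unname(g^2 * a["var"]), tolerance = 1e-12)
  expect_equal(unname(b[c("zc", "ssc")]), unname(a[c("zc", "ssc")]))
})

test_that("spectral features: tone localization, white noise, homogeneity", {
  fs <- 2222
  n <- 333
  t <- (0:(n - 1)) / fs
  tone <- sin(2 * pi * 100 * t)
  sf <- spectral_features(tone, fs)
  bin <- fs / n
  expect_lt(abs(sf["meanfreq"] - 100), bin)
  expect_lt(abs(sf["medfreq"] - 100), bin)
  expect_lt(abs(sf["peakfreq"] - 100), bin)
  expect_lt(sf["cfv"], (2 * bin)^2)

  # white noise: mean frequency ~ fs/4 within 5% averaged over 100 frames
  fr <- random_frames(100, 333, seed = 77)
  with_seed_local(78, fr <- matrix(rnorm(333 * 100), 333))
  mf <- mean(vapply(seq_len(100),
                    function(j) spectral_features(fr[, j], fs)["meanfreq"],
                    numeric(1)))
  expect_lt(abs(mf / (fs / 4) - 1), 0.05)

  g <- 2.5
  a <- spectral_features(tone, fs); b <- spectral_features(g * tone, fs)
  pow <- c("mpd", "sm1", "sm2", "sm3", "pdw")
  expect_equal(unname(b[pow]), unname(g^2 * a[pow]), tolerance = 1e-9)
  inv <- c("meanfreq", "medfreq", "peakfreq", "cfv")
  expect_equal(unname(b[inv]), unname(a[inv]), tolerance = 1e-9)

  z <- spectral_features(numeric(64), fs)
  expect_true(all(z[c("meanfreq", "medfreq", "peakfreq")] == 0))
  expect_true(all(is.finite(z)))
})

test_that("MFCC: length, gain moves only c0, tone differs from noise", {
  fs <- 2222
  with_seed_local(31, fr <- rnorm(89))
  cc <- mfcc_features(fr, fs)
  expect_length(cc, 24L)
  cg <- mfcc_features(4 * fr, fs)
  expect_equal(unname(cg[1] - cc[1]), 26 * log(4), tolerance = 1e-6)
  expect_equal(unname(cg[-1]), unname(cc[-1]), tolerance = 1e-8)
  t <- (0:88) / fs
  tone <- sin(2 * pi * 100 * t)
  with_seed_local(32, noise <- rnorm(89))
  expect_gt(abs(mfcc_features(tone, fs)[2] - mfcc_features(noise, fs)[2]), 1)
})

test_that("wavelet statistics: zeros, scaling, exact energy conservation", {
  expect_true(all(wavelet_features(numeric(89)) == 0))
  with_seed_local(41, fr <- rnorm(89))
  a <- wavelet_features(fr); b <- wavelet_features(2 * fr)
  maxes <- grep("max$", names(a)); vars <- grep("var$", names(a))
  expect_equal(unname(b[maxes]), unname(2 * a[maxes]), tolerance = 1e-12)
  expect_equal(unname(b[vars]), unname(4 * a[vars]), tolerance = 1e-12)
  # orthogonality: detail + approximation energy equals frame energy
  wm <- emg2prosody:::wavelet_features_mat(matrix(fr, ncol = 1))
  x <- c(fr, numeric(96 - 89))
  energy <- sum(x^2)
  lev_e <- 0
  xx <- matrix(x, ncol = 1)
  for (l in 1:4) {
    dec <- emg2prosody:::dwt_level_mat(xx)
    lev_e <- lev_e + sum(dec$d^2)
    xx <- dec$a
  }
  expect_equal(lev_e + sum(xx^2), energy, tolerance = 1e-8)
})

test_that("pairwise features: self-pair, shifted copies, independent noise", {
  fs <- 2222
  with_seed_local(51, {
    y <- rnorm(200)
    ch1 <- matrix(y[1:89], ncol = 1)
    ch2 <- matrix(y[6:94], ncol = 1)        # 5-sample shifted copy
  })
  pw <- pairwise_features(list(ch1, ch1), fs)
  self <- which(rownames(pw$xcorr) == "ch1.ch1")
  expect_equal(unname(pw$xcorr["ch1.ch1", 1]), 1, tolerance = 1e-9)
  expect_equal(unname(pw$coh["ch1.ch1", 1]), 1, tolerance = 1e-9)
  pw2 <- pairwise_features(list(ch1, ch2), fs)
  expect_gt(pw2$xcorr["ch1.ch2", 1], 0.9)
  # independent noise: mean coherence below the short-frame bias ceiling
  with_seed_local(52, {
    a <- matrix(rnorm(89 * 100), 89)
    b <- matrix(rnorm(89 * 100), 89)
  })
  pw3 <- pairwise_features(list(a, b), fs)
  expect_lt(mean(pw3$coh["ch1.ch2", ]), 0.35)
  # zero-variance channel flagged as 0, not NaN
  pw4 <- pairwise_features(list(matrix(0, 89, 1), ch1), fs)
  expect_equal(unname(pw4$xcorr["ch1.ch2", 1]), 0)
  expect_true(all(is.finite(unlist(pw4))))
})

test_that("assembly: dimension closed form, names, determinism", {
  # hand count at 2 channels: 2 x (6 td + 9 spectral + 24 mfcc + 12 wavelet)
  # + 3 pairwise families x 3 unordered pairs = 102 + 9 = 111
  expect_equal(feature_dimension(2), 111L)
  expect_equal(feature_dimension(8), 516L)
  with_seed_local(61, {
    tracks <- lapply(1:2, function(i)
      signal_track(rnorm(2222), 2222, channel = paste0("ch", i)))
  })
  fm <- extract_emg_features(tracks, frame_spec(0.040, 0.020))
  expect_equal(ncol(fm$values), 111L)
  expect_equal(nrow(fm$values), 49L)
  expect_false(anyDuplicated(fm$feature_names) > 0)
  # symmetric family entries only with i <= j
  pair_names <- grep("^(coh|betacoh|xcorr)", fm$feature_names, value = TRUE)
  ij <- regmatches(pair_names, gregexpr("[0-9]+", pair_names))
  expect_true(all(vapply(ij, function(v)
    as.integer(v[1]) <= as.integer(v[2]), logical(1))))
  fm2 <- extract_emg_features(tracks, frame_spec(0.040, 0.020))
  expect_identical(fm$values, fm2$values)
  expect_identical(fm$feature_names, fm2$feature_names)
})

test_that("features are finite on fuzz frames and rows are deterministic", {
  fr <- random_frames(200, 89, seed = 71)
  fs <- 2222
  td <- emg2prosody:::td_features_mat(fr)
  sp <- emg2prosody:::spectral_features_mat(fr, fs)
  mf <- emg2prosody:::mfcc_features_mat(fr, fs)
  wv <- emg2prosody:::wavelet_features_mat(fr)
  expect_true(all(is.finite(td)), all(is.finite(sp)))
  expect_true(all(is.finite(mf)), all(is.finite(wv)))
  # identical frames give identical rows
  expect_identical(emg2prosody:::td_features_mat(fr[, c(1, 1)])[, 1],
                   emg2prosody:::td_features_mat(fr[, c(1, 1)])[, 2])
})

test_that("feature matrix serializes and pairs with frame targets", {
  with_seed_local(81, tracks <- lapply(1:2, function(i)
    signal_track(rnorm(4444), 2222)))
  fm <- extract_emg_features(tracks, frame_spec(0.040, 0.020))
  f <- tempfile(fileext = ".tsv")
  write_feature_matrix(fm, f)
  fm2 <- read_feature_matrix(f)
  expect_equal(fm2$values, fm$values, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(fm2$feature_names, fm$feature_names)
  unlink(f)
  # time-grid agreement with frame_targets to 1e-9
  cont <- contour(seq(0, 1.995, by = 0.005), rep(100, 400), "Hz")
  tg <- frame_targets(cont, 0.040, 0.020)
  n <- min(length(tg$times), length(fm$frame_centers))
  expect_lt(max(abs(tg$times[seq_len(n)] - fm$frame_centers[seq_len(n)])),
            1e-9)
})
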