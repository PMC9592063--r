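# The per-frame sEMG feature battery: six time-domain statistics, nine
# spectral statistics from the one-sided periodogram, 24 MFCCs, twelve
# Daubechies-2 wavelet statistics (per channel), and three cross-channel
# families (coherence, beta-band coherence, peak normalized
# cross-correlation) over unordered channel pairs. Internals are vectorized
# over frames (frames as matrix columns); the exported per-frame operations
# wrap the same code paths.

#' Framing specification
#'
#' 40 ms / 20 ms is the f0 stream; 150 ms / 30 ms the intensity stream.
#'
#' @param frame_len frame length (s).
#' @param step frame step (s), `0 < step <= frame_len`.
#' @return an object of class `frame_spec`.
#' @export
frame_spec <- function(frame_len, step) {
  stopifnot(frame_len > 0, step > 0, step <= frame_len)
  structure(list(frame_len = frame_len, step = step), class = "frame_spec")
}

#' Cut a track into fixed-length frames
#'
#' Frame `k` (1-based) starts at `(k-1) * step`; the trailing partial frame
#' is dropped.
#'
#' @param track a `signal_track`.
#' @param spec a [frame_spec()].
#' @return a list with `frames` (samples x n_frames matrix), `times` (frame
#'   start times, s), `centers` (frame centres, s). Too-short tracks yield
#'   zero frames.
#' @export
frame_signal <- function(track, spec) {
  stopifnot(inherits(track, "signal_track"), inherits(spec, "frame_spec"))
  fs <- track$rate
  nw <- round(spec$frame_len * fs)
  n <- length(track$samples)
  if (n < nw)
    return(list(frames = matrix(numeric(0), nrow = nw), times = numeric(0),
                centers = numeric(0)))
  # start indices are rounded per frame from the exact k * step times, so
  # the frame grid never drifts from the target-contour grid
  nf <- floor((n / fs - spec$frame_len) / spec$step + 1e-9) + 1L
  starts <- round((seq_len(nf) - 1L) * spec$step * fs)
  while (nf > 0L && starts[nf] + nw > n) {
    nf <- nf - 1L; starts <- starts[seq_len(nf)]
  }
  if (nf == 0L)
    return(list(frames = matrix(numeric(0), nrow = nw), times = numeric(0),
                centers = numeric(0)))
  idx <- outer(seq_len(nw), starts, `+`)
  list(frames = matrix(track$samples[idx], nrow = nw),
       times = (seq_len(nf) - 1) * spec$step,
       centers = (seq_len(nf) - 1) * spec$step + spec$frame_len / 2)
}

# ---- time domain ----------------------------------------------------------

# matrix internals: frames as columns
td_features_mat <- function(fr, eps_factor = 0.01) {
  n <- nrow(fr)
  mav <- colMeans(abs(fr))
  ms <- colMeans(fr^2)
  rms <- sqrt(ms)
  v <- ms - colMeans(fr)^2            # population variance
  d <- fr[-1, , drop = FALSE] - fr[-n, , drop = FALSE]
  wl <- colSums(abs(d))
  eps <- eps_factor * rms             # dead-band per frame
  epsm <- matrix(eps, n - 1, length(eps), byrow = TRUE)
  s <- sign(fr)
  zc <- colSums((s[-1, , drop = FALSE] * s[-n, , drop = FALSE] < 0) &
                  (abs(d) > epsm))
  d2 <- d[-1, , drop = FALSE] * d[-(n - 1), , drop = FALSE]
  epsm2 <- epsm[-1, , drop = FALSE]
  ssc <- colSums((d2 < 0) & (abs(d[-1, , drop = FALSE]) > epsm2 |
                               abs(d[-(n - 1), , drop = FALSE]) > epsm2))
  rbind(mav = mav, rms = rms, var = v, wl = wl, zc = zc, ssc = ssc)
}

#' Time-domain sEMG features of one frame
#'
#' Mean absolute value, RMS, population variance, waveform length, and
#' zero-crossing / slope-sign-change counts with a dead-band of
#' `eps_factor` times the frame RMS.
#'
#' @param frame numeric vector (length >= 3).
#' @param eps_factor dead-band as a fraction of frame RMS (default 0.01).
#' @return named numeric vector `mav, rms, var, wl, zc, ssc`.
#' @export
time_domain_features <- function(frame, eps_factor = 0.01) {
  stopifnot(length(frame) >= 3L)
  m <- td_features_mat(matrix(frame, ncol = 1), eps_factor)
  setNames(m[, 1], rownames(m))
}

# ---- spectral -------------------------------------------------------------

# one-sided periodogram of frame columns: list(P = bins x frames, f = Hz)
periodogram_mat <- function(fr, fs) {
  n <- nrow(fr)
  X <- mvfft(fr)
  n2 <- n %/% 2L + 1L
  P <- Mod(X[seq_len(n2), , drop = FALSE])^2 / n
  list(P = P, f = (seq_len(n2) - 1) * fs / n)
}

spectral_features_mat <- function(fr, fs) {
  pg <- periodogram_mat(fr, fs)
  P <- pg$P; f <- pg$f
  tot <- colSums(P)
  safe <- tot > 0
  tot[!safe] <- 1
  meanf <- colSums(P * f) / tot
  cum <- apply(P, 2, cumsum)
  medf <- f[max.col(t(cum >= rep(tot / 2, each = nrow(P))), "first")]
  peakf <- f[max.col(t(P), "first")]
  mpd <- colMeans(P)
  cfv <- vapply(seq_len(ncol(P)), function(j)
    sum(P[, j] * (f - meanf[j])^2) / tot[j], numeric(1))
  sm1 <- colSums(P * f)
  sm2 <- colSums(P * f^2)
  sm3 <- colSums(P * f^3)
  pdw <- colSums(abs(P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE]))
  z <- !safe
  meanf[z] <- 0; medf[z] <- 0; peakf[z] <- 0; cfv[z] <- 0
  rbind(meanfreq = meanf, medfreq = medf, peakfreq = peakf, mpd = mpd,
        cfv = cfv, sm1 = sm1, sm2 = sm2, sm3 = sm3, pdw = pdw)
}

#' Spectral sEMG features of one frame
#'
#' From the one-sided periodogram P(f): mean / median / peak frequency, mean
#' power density, central frequency variance, unnormalized spectral moments
#' `SM_k = sum(P * f^k)` for k = 1..3, and the power-density wavelength
#' `sum(|P_{j+1} - P_j|)`. An all-zero frame returns zeros.
#'
#' @param frame numeric vector (length >= 16).
#' @param fs sampling rate (Hz).
#' @return named numeric vector of 9 features.
#' @export
spectral_features <- function(frame, fs) {
  stopifnot(length(frame) >= 16L)
  m <- spectral_features_mat(matrix(frame, ncol = 1), fs)
  setNames(m[, 1], rownames(m))
}

# ---- MFCC -----------------------------------------------------------------

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

mel_filterbank <- function(n_filters, n_bins, fs, nfft) {
  pts <- mel_to_hz(seq(0, hz_to_mel(fs / 2), length.out = n_filters + 2))
  bins <- pts / (fs / nfft)
  fb <- matrix(0, n_filters, n_bins)
  k <- seq_len(n_bins) - 1
  for (m in seq_len(n_filters)) {
    lo <- bins[m]; mid <- bins[m + 1]; hi <- bins[m + 2]
    up <- (k - lo) / max(mid - lo, 1e-9)
    dn <- (hi - k) / max(hi - mid, 1e-9)
    fb[m, ] <- pmax(0, pmin(up, dn))
  }
  fb
}

mfcc_features_mat <- function(fr, fs, n_coeff = 24L, n_filters = 26L) {
  n <- nrow(fr)
  nfft <- 2^ceiling(log2(n))
  pad <- rbind(fr, matrix(0, nfft - n, ncol(fr)))
  n2 <- nfft %/% 2L + 1L
  mag <- Mod(mvfft(pad)[seq_len(n2), , drop = FALSE])
  fb <- mel_filterbank(n_filters, n2, fs, nfft)
  E <- log(fb %*% mag + 1e-30)
  m <- seq_len(n_filters) - 0.5
  dct <- outer(0:(n_coeff - 1), m, function(k, mm)
    cos(pi * k * mm / n_filters))
  cc <- dct %*% E
  rownames(cc) <- sprintf("mfcc%02d", seq_len(n_coeff))
  cc
}

#' Mel-frequency cepstral coefficients of one frame
#'
#' Triangular mel filterbank (26 filters spanning 0 to fs/2) on the
#' zero-padded magnitude spectrum, log, then DCT-II; the first `n_coeff`
#' coefficients including c0 are returned. A pure gain between two frames
#' moves only c0.
#'
#' @param frame numeric vector (length >= 32).
#' @param fs sampling rate (Hz).
#' @param n_coeff number of coefficients (default 24).
#' @return numeric vector of length `n_coeff`.
#' @export
mfcc_features <- function(frame, fs, n_coeff = 24L) {
  stopifnot(length(frame) >= 32L)
  m <- mfcc_features_mat(matrix(frame, ncol = 1), fs, n_coeff)
  setNames(m[, 1], rownames(m))
}

# ---- wavelets -------------------------------------------------------------

# Daubechies-2 (D4) analysis filters
DB2_LO <- c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
DB2_HI <- rev(DB2_LO) * c(1, -1, 1, -1)

# one periodic DWT level on frame columns (n even): list(approx, detail)
dwt_level_mat <- function(x) {
  n <- nrow(x)
  half <- n %/% 2L
  a <- matrix(0, half, ncol(x)); d <- matrix(0, half, ncol(x))
  for (j in 0:3) {
    idx <- ((2 * (seq_len(half) - 1L) + j) %% n) + 1L
    a <- a + DB2_LO[j + 1] * x[idx, , drop = FALSE]
    d <- d + DB2_HI[j + 1] * x[idx, , drop = FALSE]
  }
  list(a = a, d = d)
}

wavelet_features_mat <- function(fr, n_levels = 4L) {
  n <- nrow(fr)
  target <- 2^n_levels * ceiling(n / 2^n_levels)  # zero-pad to multiple
  if (target > n) fr <- rbind(fr, matrix(0, target - n, ncol(fr)))
  out <- matrix(0, 3L * n_levels, ncol(fr))
  x <- fr
  for (lev in seq_len(n_levels)) {
    dec <- dwt_level_mat(x)
    d <- dec$d
    out[3 * lev - 2, ] <- apply(abs(d), 2, max)
    out[3 * lev - 1, ] <- colMeans(d)
    out[3 * lev, ] <- colMeans(d^2) - colMeans(d)^2
    x <- dec$a
  }
  rownames(out) <- as.vector(t(outer(paste0("db2l", seq_len(n_levels)),
                                     c("max", "mean", "var"), paste,
                                     sep = "")))
  attr(out, "approx") <- x
  out
}

#' Daubechies-2 wavelet statistics of one frame
#'
#' Four-level periodized orthogonal DWT with the db2 filter pair (frames are
#' zero-padded to a multiple of 16, so the transform conserves energy
#' exactly); per detail level d1..d4 the maximum absolute coefficient, the
#' mean, and the population variance.
#'
#' @param frame numeric vector.
#' @return named numeric vector of 12 values (levels x statistics).
#' @export
wavelet_features <- function(frame) {
  m <- wavelet_features_mat(matrix(frame, ncol = 1))
  setNames(m[, 1], rownames(m))
}

# ---- pairwise families ----------------------------------------------------

# Welch spectra of all frames of all channels; returns array
# [bin, segment-averaged channel spectra] as a list per channel plus cross
welch_segments <- function(fr, seg_len = 32L, overlap = 16L) {
  n <- nrow(fr)
  starts <- seq(1L, n - seg_len + 1L, by = seg_len - overlap)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(seg_len) - 1) / (seg_len - 1))
  segs <- lapply(starts, function(s) fr[s:(s + seg_len - 1L), , drop = FALSE] * w)
  lapply(segs, mvfft)   # list over segments: seg_len x n_frames complex
}

#' Cross-channel features for framed multichannel sEMG
#'
#' For every unordered channel pair (self-pairs included): magnitude-squared
#' coherence averaged over 20-450 Hz and over the beta band 15-30 Hz (Welch
#' within the frame, segment length 32, overlap 16; a band that contains no
#' full bin centre uses the bins overlapping it), and the maximum of the
#' normalized cross-correlation over lags within half the frame length.
#'
#' @param frames_by_channel list (one per channel) of samples x n_frames
#'   matrices, identically framed.
#' @param fs sampling rate (Hz).
#' @return a list of three `n_pairs x n_frames` matrices `coh`, `betacoh`,
#'   `xcorr`, with rownames `chI.chJ` (I <= J).
#' @export
pairwise_features <- function(frames_by_channel, fs) {
  nc <- length(frames_by_channel)
  nf <- ncol(frames_by_channel[[1]])
  n <- nrow(frames_by_channel[[1]])
  stopifnot(all(vapply(frames_by_channel, nrow, 0L) == n),
            all(vapply(frames_by_channel, ncol, 0L) == nf))
  seg_len <- 32L
  f_seg <- (seq_len(seg_len %/% 2L + 1L) - 1) * fs / seg_len
  band_bins <- function(lo, hi) {
    df <- fs / seg_len
    sel <- which(f_seg >= lo & f_seg <= hi)
    if (!length(sel)) sel <- which(f_seg + df / 2 > lo & f_seg - df / 2 < hi)
    sel
  }
  bins_main <- band_bins(20, 450)
  bins_beta <- band_bins(15, 30)
  segs <- lapply(frames_by_channel, welch_segments, seg_len = seg_len)
  nseg <- length(segs[[1]])
  n2 <- seg_len %/% 2L + 1L
  # segment-averaged auto/cross spectra per pair
  auto <- lapply(seq_len(nc), function(ch) {
    acc <- matrix(0, n2, nf)
    for (s in seq_len(nseg))
      acc <- acc + Mod(segs[[ch]][[s]][seq_len(n2), , drop = FALSE])^2
    acc / nseg
  })
  pairs <- which(upper.tri(diag(nc), diag = TRUE), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  np <- nrow(pairs)
  coh <- matrix(0, np, nf); betacoh <- matrix(0, np, nf)
  xc <- matrix(0, np, nf)
  # cross-correlation via FFT, lags limited to +/- n/2
  nfft <- 2^ceiling(log2(2L * n))
  Xp <- lapply(frames_by_channel, function(fr)
    mvfft(rbind(fr, matrix(0, nfft - n, nf))))
  energy <- matrix(vapply(frames_by_channel, function(fr) colSums(fr^2),
                          numeric(nf)), nrow = nf)
  max_lag <- n %/% 2L
  lag_rows <- c(seq_len(max_lag + 1L), nfft - seq_len(max_lag) + 1L)
  for (p in seq_len(np)) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    cross <- matrix(0 + 0i, n2, nf)
    for (s in seq_len(nseg))
      cross <- cross + Conj(segs[[i]][[s]][seq_len(n2), , drop = FALSE]) *
        segs[[j]][[s]][seq_len(n2), , drop = FALSE]
    cross <- cross / nseg
    den <- auto[[i]] * auto[[j]]
    C <- Mod(cross)^2 / pmax(den, 1e-300)
    C[den <= 1e-300] <- 0
    coh[p, ] <- colMeans(C[bins_main, , drop = FALSE])
    betacoh[p, ] <- colMeans(C[bins_beta, , drop = FALSE])
    cc <- Re(mvfft(Conj(Xp[[i]]) * Xp[[j]], inverse = TRUE)) / nfft
    peak <- apply(abs(cc[lag_rows, , drop = FALSE]), 2, max)
    norm <- sqrt(energy[, i] * energy[, j])
    ok <- norm > 1e-300
    xc[p, ok] <- peak[ok] / norm[ok]
  }
  rn <- sprintf("ch%d.ch%d", pairs[, 1], pairs[, 2])
  rownames(coh) <- rn; rownames(betacoh) <- rn; rownames(xc) <- rn
  list(coh = coh, betacoh = betacoh, xcorr = xc)
}

# ---- assembly -------------------------------------------------------------

#' Number of features the battery realizes
#'
#' Per channel: 6 time-domain + 9 spectral + 24 MFCC + 12 wavelet = 51;
#' plus 3 pairwise families over the `n (n + 1) / 2` unordered channel pairs
#' (symmetric duplicates removed, self-pairs kept).
#'
#' @param n_channels channel count.
#' @return integer feature dimension.
#' @export
feature_dimension <- function(n_channels)
  as.integer(51L * n_channels + 3L * n_channels * (n_channels + 1L) / 2L)

#' Extract the full feature battery from multichannel sEMG
#'
#' Frames every channel with the same [frame_spec()], computes all 20
#' feature families, removes symmetric-pair duplicates, and cascades
#' everything into one frames x features matrix with deterministic naming
#' and column order (per-channel families by channel, then the pairwise
#' families by pair).
#'
#' @param emg_tracks list of `signal_track`s at a common rate.
#' @param spec a [frame_spec()].
#' @param eps_factor dead-band factor for ZC/SSC (default 0.01).
#' @return a list of class `feature_matrix`: `values` (frames x features),
#'   `frame_times` (frame start times, s), `frame_centers`, `feature_names`,
#'   `n_channels`, `spec`.
#' @export
extract_emg_features <- function(emg_tracks, spec, eps_factor = 0.01) {
  stopifnot(length(emg_tracks) >= 1L)
  fs <- emg_tracks[[1]]$rate
  stopifnot(all(vapply(emg_tracks, `[[`, 0, "rate") == fs))
  framed <- lapply(emg_tracks, frame_signal, spec = spec)
  nf <- length(framed[[1]]$times)
  if (nf == 0L) stopf("extract_emg_features: track shorter than one frame")
  stopifnot(all(vapply(framed, function(f) length(f$times), 0L) == nf))
  frames_by_channel <- lapply(framed, `[[`, "frames")
  nch <- length(emg_tracks)
  blocks <- list(); names_out <- character(0)
  for (ch in seq_len(nch)) {
    fr <- frames_by_channel[[ch]]
    blk <- rbind(td_features_mat(fr, eps_factor),
                 spectral_features_mat(fr, fs),
                 mfcc_features_mat(fr, fs),
                 wavelet_features_mat(fr))
    rownames(blk) <- paste0(rownames(blk), ".ch", ch)
    blocks[[length(blocks) + 1L]] <- blk
  }
  pw <- pairwise_features(frames_by_channel, fs)
  for (fam in c("coh", "betacoh", "xcorr")) {
    blk <- pw[[fam]]
    rownames(blk) <- paste0(fam, ".", rownames(blk))
    blocks[[length(blocks) + 1L]] <- blk
  }
  values <- t(do.call(rbind, blocks))
  if (anyDuplicated(colnames(values)))
    stopf("extract_emg_features: duplicated feature names")
  structure(list(values = values, frame_times = framed[[1]]$times,
                 frame_centers = framed[[1]]$centers,
                 feature_names = colnames(values), n_channels = nch,
                 spec = spec),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d frames x %d features (%d channels)\n",
              nrow(x$values), ncol(x$values), x$n_channels))
  invisible(x)
}

#' Write / read a feature matrix as delimited text with a names header
#' @param fm a `feature_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  d <- data.frame(frame_time_s = fm$frame_times, fm$values,
                  check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_channels: %d; frame_len_s: %g; step_s: %g; dim: %d",
                     fm$n_channels, fm$spec$frame_len, fm$spec$step,
                     ncol(fm$values)), con)
  write.table(format(d, digits = 10, trim = TRUE), con, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, gregexpr("[0-9.]+", hdr))[[1]]
  d <- read.table(path, header = TRUE, sep = "\t", skip = 1L,
                  check.names = FALSE)
  vals <- as.matrix(d[, -1, drop = FALSE])
  spec <- frame_spec(as.numeric(m[2]), as.numeric(m[3]))
  structure(list(values = vals, frame_times = d[[1]],
                 frame_centers = d[[1]] + spec$frame_len / 2,
                 feature_names = colnames(vals),
                 n_channels = as.integer(m[1]), spec = spec),
            class = "feature_matrix")
}
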