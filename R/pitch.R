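# Autocorrelation pitch tracking: per-frame candidate generation from the
# window-corrected normalized autocorrelation, then a dynamic-programming
# path over candidates with octave / octave-jump / voiced-unvoiced costs.

#' Pitch tracker parameters
#'
#' The floor/ceiling default to 65 and 475 Hz; the analysis time step to
#' `0.75 / f_min`. Path-finder costs default to the published defaults of the
#' standard autocorrelation tracker (silence 0.03, voicing 0.45, octave 0.01,
#' octave-jump 0.35, voiced/unvoiced 0.14).
#'
#' @param f_min pitch floor (Hz).
#' @param f_max pitch ceiling (Hz).
#' @param time_step analysis step (s); default `0.75 / f_min`.
#' @param silence_threshold,voicing_threshold,octave_cost,octave_jump_cost,voiced_unvoiced_cost
#'   dimensionless path costs.
#' @param max_candidates voiced candidates kept per frame.
#' @return an object of class `pitch_params`.
#' @export
pitch_params <- function(f_min = 65, f_max = 475, time_step = 0.75 / f_min,
                         silence_threshold = 0.03, voicing_threshold = 0.45,
                         octave_cost = 0.01, octave_jump_cost = 0.35,
                         voiced_unvoiced_cost = 0.14, max_candidates = 15L) {
  stopifnot(f_min > 0, f_min < f_max, time_step > 0)
  structure(list(f_min = f_min, f_max = f_max, time_step = time_step,
                 silence_threshold = silence_threshold,
                 voicing_threshold = voicing_threshold,
                 octave_cost = octave_cost,
                 octave_jump_cost = octave_jump_cost,
                 voiced_unvoiced_cost = voiced_unvoiced_cost,
                 max_candidates = as.integer(max_candidates)),
            class = "pitch_params")
}

#' Extract the f0 contour from audio
#'
#' Frames of length `3 / f_min` are Gaussian-tapered; for each frame the
#' normalized autocorrelation is divided by the window's autocorrelation and
#' its local maxima within the \[1/f_max, 1/f_min\] lag range (refined by
#' parabolic interpolation) become voiced pitch candidates, alongside one
#' unvoiced candidate whose strength grows as the frame gets quiet. The
#' returned contour is the least-cost candidate path.
#'
#' @param audio a `signal_track` with `rate >= 4 * f_max`.
#' @param params a [pitch_params()].
#' @return a `contour` in Hz on the `time_step` grid; `NA` where the path is
#'   unvoiced. Too-short input yields an empty contour.
#' @export
extract_f0 <- function(audio, params = pitch_params()) {
  stopifnot(inherits(audio, "signal_track"), inherits(params, "pitch_params"))
  fs <- audio$rate
  if (fs < 4 * params$f_max)
    stopf("extract_f0: sampling rate %g too low for f_max %g", fs,
          params$f_max)
  x <- audio$samples
  dur <- length(x) / fs
  wdur <- 3 / params$f_min
  nw <- round(wdur * fs)
  if (length(x) < nw) return(contour(numeric(0), numeric(0), "Hz"))

  nf <- floor((dur - wdur) / params$time_step) + 1L
  # centre the frame sequence in the signal
  t0 <- (dur - wdur - (nf - 1) * params$time_step) / 2
  centers <- t0 + wdur / 2 + (seq_len(nf) - 1) * params$time_step
  starts <- round((centers - wdur / 2) * fs) + 1L

  # Gaussian taper and its autocorrelation (for the window correction)
  u <- (seq_len(nw) - 0.5) / nw
  w <- (exp(-12 * (u - 0.5)^2) - exp(-12)) / (1 - exp(-12))
  nfft <- 2^ceiling(log2(1.5 * nw))
  rw <- Re(fft(Mod(fft(c(w, numeric(nfft - nw))))^2, inverse = TRUE))
  rw <- rw / rw[1]

  lag_min <- max(2L, floor(fs / params$f_max))
  lag_max <- min(nw - 1L, ceiling(fs / params$f_min))
  global_peak <- max(abs(x - mean(x)), 1e-30)
  n_cand <- params$max_candidates

  cand_f <- matrix(NA_real_, nf, n_cand)      # candidate frequency (NA = uv)
  cand_R <- matrix(-Inf, nf, n_cand)          # candidate strength

  chunk <- 256L
  for (c0 in seq(1L, nf, by = chunk)) {
    idx <- c0:min(c0 + chunk - 1L, nf)
    seg <- vapply(starts[idx], function(s)
      x[s:(s + nw - 1L)], numeric(nw))
    seg <- sweep(seg, 2, colMeans(seg))
    local_peak <- apply(abs(seg), 2, max)
    segw <- seg * w
    pad <- rbind(segw, matrix(0, nfft - nw, length(idx)))
    R <- Re(mvfft(Mod(mvfft(pad))^2, inverse = TRUE))
    R0 <- pmax(R[1, ], 1e-300)
    for (j in seq_along(idx)) {
      ra <- (R[seq_len(lag_max + 2L), j] / R0[j]) /
        pmax(rw[seq_len(lag_max + 2L)], 1e-12)
      i <- idx[j]
      # unvoiced candidate
      uv <- params$voicing_threshold +
        max(0, 2 - (local_peak[j] / global_peak) /
              (params$silence_threshold / (1 + params$voicing_threshold)))
      cand_f[i, 1] <- NA_real_
      cand_R[i, 1] <- uv
      # local maxima in the admissible lag range
      lag_idx <- (lag_min + 1L):(lag_max + 1L)   # ra index = lag + 1
      v <- ra[lag_idx]
      is_max <- v > c(-Inf, head(v, -1)) & v >= c(tail(v, -1), -Inf) & v > 0.1
      peaks <- which(is_max)
      if (length(peaks)) {
        # rank by octave-bonus-adjusted strength, not raw correlation:
        # for near-periodic signals all period multiples correlate ~1 and
        # the subharmonics would otherwise crowd out the true lag
        adj <- v[peaks] - params$octave_cost *
          log2(params$f_min * (lag_idx[peaks] - 1L) / fs)
        ord <- order(adj, decreasing = TRUE)
        peaks <- peaks[head(ord, n_cand - 1L)]
        for (k in seq_along(peaks)) {
          li <- lag_idx[peaks[k]]          # index into ra
          lag <- li - 1L
          # parabolic refinement
          if (li > 2L && li < length(ra)) {
            y1 <- ra[li - 1L]; y2 <- ra[li]; y3 <- ra[li + 1L]
            den <- y1 - 2 * y2 + y3
            d <- if (abs(den) > 1e-12) 0.5 * (y1 - y3) / den else 0
            d <- max(min(d, 0.5), -0.5)
            lag_r <- lag + d
            str <- y2 - 0.25 * (y1 - y3) * d
          } else { lag_r <- lag; str <- ra[li] }
          f <- fs / lag_r
          # interpolation can push a boundary candidate marginally past the
          # floor/ceiling; clamp within 1% rather than dropping it
          if (f < params$f_min * 0.99 || f > params$f_max * 1.01) next
          f <- min(max(f, params$f_min), params$f_max)
          if (str > 1) str <- 1 / str     # spurious > 1 correlations
          cand_f[i, k + 1L] <- f
          cand_R[i, k + 1L] <- str -
            params$octave_cost * log2(params$f_min * lag_r / fs)
        }
      }
    }
  }

  path <- pitch_viterbi(cand_f, cand_R, params)
  vals <- vapply(seq_len(nf), function(i) cand_f[i, path[i]], numeric(1))
  contour(centers, vals, "Hz")
}

# least-cost path over per-frame candidates (vectorized transitions)
pitch_viterbi <- function(cand_f, cand_R, params) {
  nf <- nrow(cand_f); nc <- ncol(cand_f)
  cost <- matrix(Inf, nf, nc)
  back <- matrix(1L, nf, nc)
  ok1 <- is.finite(cand_R[1, ])
  cost[1, ok1] <- -cand_R[1, ok1]
  for (i in 2:nf) {
    fp <- cand_f[i - 1, ]; fv <- cand_f[i, ]
    lp <- log2(fp); lv <- log2(fv)
    # transition cost matrix: previous candidates (rows) x current (cols)
    trans <- params$octave_jump_cost * abs(outer(lp, lv, `-`))
    uv_p <- is.na(fp); uv_v <- is.na(fv)
    trans[uv_p, ] <- params$voiced_unvoiced_cost
    trans[, uv_v] <- params$voiced_unvoiced_cost
    trans[uv_p, uv_v] <- 0
    tot <- cost[i - 1, ] + trans
    tot[!is.finite(tot)] <- Inf
    p_best <- max.col(-t(tot), "first")
    ok <- is.finite(cand_R[i, ])
    cost[i, ok] <- tot[cbind(p_best[ok], which(ok))] - cand_R[i, ok]
    back[i, ] <- p_best
  }
  path <- integer(nf)
  path[nf] <- which.min(cost[nf, ])
  if (nf > 1) for (i in nf:2) path[i - 1] <- back[i, path[i]]
  path
}
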