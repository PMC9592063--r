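# Intensity contour extraction (squared signal smoothed by a unit-area
# Kaiser window), dB SPL calibration, semitone conversion, and frame-level
# target averaging.

# Kaiser window via the modified Bessel function I0 (series expansion)
bessel_i0 <- function(x) {
  out <- numeric(length(x))
  term <- rep(1, length(x)); s <- rep(1, length(x))
  hx2 <- (x / 2)^2
  for (k in 1:60) {
    term <- term * hx2 / k^2
    s <- s + term
  }
  s
}

kaiser_window <- function(n, beta) {
  m <- n - 1
  k <- 0:m
  bessel_i0(beta * sqrt(pmax(1 - ((2 * k - m) / m)^2, 0))) / bessel_i0(beta)
}

INTENSITY_P_REF <- 4e-10     # reference power: full-scale sine -> ~91 dB
INTENSITY_DB_FLOOR <- -200   # guard for silent spans (never -Inf)

#' Extract the intensity contour from audio
#'
#' The mean-subtracted signal is squared and convolved with a unit-area
#' Kaiser window (shape parameter high enough that sidelobes sit far below
#' -190 dB) of duration `3.2 / f_min`; the smoothed power is sampled on a
#' regular grid and converted to dB against a reference under which a
#' full-scale sine reads about 91 dB.
#'
#' @param audio a `signal_track`.
#' @param f_min pitch floor (Hz); sets the window duration (default 65).
#' @param time_step contour step (s); default `0.8 / f_min` (a quarter
#'   window).
#' @param beta Kaiser shape parameter (default `20 * pi / sqrt(2)`).
#' @return a `contour` in dB (uncalibrated). All-silent spans are clamped at
#'   the documented floor of -200 dB rather than -Inf.
#' @export
extract_intensity <- function(audio, f_min = 65, time_step = 0.8 / f_min,
                              beta = 20 * pi / sqrt(2)) {
  stopifnot(inherits(audio, "signal_track"), f_min > 0)
  fs <- audio$rate
  x <- audio$samples - mean(audio$samples)   # DC removal before squaring
  wdur <- 3.2 / f_min
  nw <- round(wdur * fs)
  if (length(x) < nw) stopf("extract_intensity: input shorter than window")
  w <- kaiser_window(nw, beta)
  w <- w / sum(w)
  dur <- length(x) / fs
  nf <- floor((dur - wdur) / time_step) + 1L
  t0 <- (dur - wdur - (nf - 1) * time_step) / 2
  centers <- t0 + wdur / 2 + (seq_len(nf) - 1) * time_step
  starts <- round((centers - wdur / 2) * fs) + 1L
  x2 <- x^2
  p <- vapply(starts, function(s) sum(w * x2[s:(s + nw - 1L)]), numeric(1))
  db <- 10 * log10(pmax(p, INTENSITY_P_REF * 10^(INTENSITY_DB_FLOOR / 10)) /
                     INTENSITY_P_REF)
  contour(centers, db, "dB")
}

#' Microphone SPL calibration info
#'
#' Built from a sound-level-meter reading taken while a reference signal
#' plays, paired with the level the uncalibrated recording chain measured
#' for the same signal. The additive offset maps recorded dB to dB SPL.
#'
#' @param meter_reading meter value in dB SPL.
#' @param measured_level uncalibrated recorded level in dB.
#' @return an object of class `calibration_info` with the `offset` field.
#' @export
calibration_info <- function(meter_reading, measured_level) {
  stopifnot(is_scalar_num(meter_reading), is_scalar_num(measured_level))
  structure(list(meter_reading = meter_reading,
                 measured_level = measured_level,
                 offset = meter_reading - measured_level),
            class = "calibration_info")
}

#' Calibrate an intensity contour to dB SPL (or invert)
#'
#' @param cont a `contour` in dB (or dB SPL when `inverse = TRUE`).
#' @param cal a [calibration_info()].
#' @param inverse undo a previous calibration.
#' @return the shifted contour with the unit tag switched.
#' @export
calibrate_spl <- function(cont, cal, inverse = FALSE) {
  stopifnot(inherits(cont, "contour"), inherits(cal, "calibration_info"))
  want <- if (inverse) "dB SPL" else "dB"
  if (!identical(cont$unit, want))
    stopf("calibrate_spl: expected a contour in %s, got %s", want, cont$unit)
  s <- if (inverse) -cal$offset else cal$offset
  contour(cont$times, cont$values + s, if (inverse) "dB" else "dB SPL")
}

#' Convert frequency to semitones relative to a reference
#'
#' `ST = 12 * log2(f / f_ref)`; one octave is exactly 12 ST.
#'
#' @param f frequency in Hz (positive; `NA` passes through).
#' @param f_ref reference frequency in Hz.
#' @return semitones.
#' @export
hz_to_semitones <- function(f, f_ref) {
  stopifnot(is_scalar_num(f_ref), f_ref > 0)
  if (any(!is.na(f) & f <= 0)) stopf("hz_to_semitones: f must be positive")
  12 * log2(f / f_ref)
}

#' @rdname hz_to_semitones
#' @param st semitones.
#' @export
semitones_to_hz <- function(st, f_ref) {
  stopifnot(is_scalar_num(f_ref), f_ref > 0)
  f_ref * 2^(st / 12)
}

#' Average a contour into analysis frames
#'
#' Frames of length `frame_len` start at multiples of `step` (40 ms / 20 ms
#' for the f0 stream; 150 ms / 30 ms for intensity). Each frame's value is
#' the mean of the defined contour samples it covers; a frame whose defined
#' coverage falls below `min_coverage` is marked undefined (f0 frames are
#' dropped downstream where undefined, since f0 only exists during voiced
#' speech).
#'
#' Frame `k` (1-based) covers the absolute time window
#' `[(k-1) * step, (k-1) * step + frame_len)` counted from `origin`, the
#' same grid [frame_signal()] uses for the sEMG stream, so target frames
#' pair one-to-one with feature frames.
#'
#' @param cont a `contour`.
#' @param frame_len frame length (s).
#' @param step frame step (s), `step <= frame_len`.
#' @param min_coverage minimum fraction of defined samples (default 0.5).
#' @param origin absolute start time of frame 1 (default 0).
#' @return a `contour` of per-frame means with times at frame centres.
#' @export
frame_targets <- function(cont, frame_len, step, min_coverage = 0.5,
                          origin = 0) {
  stopifnot(inherits(cont, "contour"), frame_len >= step, step > 0)
  n <- length(cont$times)
  if (n == 0L) return(contour(numeric(0), numeric(0), cont$unit))
  dt <- if (n > 1) cont$times[2] - cont$times[1] else frame_len
  t_end <- cont$times[n]
  nf <- floor((t_end - origin - frame_len) / step + 1e-9) + 2L
  while (nf > 0L && (nf - 1) * step + origin + frame_len > t_end + dt + 1e-9)
    nf <- nf - 1L
  if (nf < 1L) return(contour(numeric(0), numeric(0), cont$unit))
  starts <- origin + (seq_len(nf) - 1) * step
  # index range of contour samples in [start, start + frame_len)
  i_lo <- pmax(ceiling((starts - cont$times[1] - 1e-9) / dt) + 1, 1)
  i_hi <- pmin(ceiling((starts + frame_len - cont$times[1] - 1e-9) / dt),
               n)
  def <- !is.na(cont$values)
  cs_def <- c(0, cumsum(def))
  cs_val <- c(0, cumsum(ifelse(def, cont$values, 0)))
  n_def <- cs_def[pmax(i_hi + 1, 1)] - cs_def[pmin(i_lo, n + 1)]
  s_val <- cs_val[pmax(i_hi + 1, 1)] - cs_val[pmin(i_lo, n + 1)]
  expected <- max(1, round(frame_len / dt))
  cov <- pmin(n_def / expected, 1)
  empty <- i_hi < i_lo
  vals <- ifelse(!empty & cov >= min_coverage & n_def > 0, s_val / n_def,
                 NA_real_)
  contour(starts + frame_len / 2, vals, cont$unit)
}
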