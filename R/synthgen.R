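# Synthetic recording sessions: voiced audio with known f0/intensity ground
# truth, coupled 8-channel sEMG, and task labels. The coupling (per-channel
# softplus of an affine mix of pitch deviation, intensity deviation and
# voicing) is the stand-in for extrinsic laryngeal / facial muscle activity
# scaling with prosody; it makes every downstream stage testable against
# known truth without access to human recordings.

TASK_TYPES <- c("tone", "legato", "vcv", "phrase", "passage", "question",
                "monologue")

# default durations (s), roughly proportional to how long each task type runs
# in a session (passages longest, vcv shortest)
TASK_DURATIONS <- c(tone = 4, legato = 5, vcv = 3, phrase = 5, passage = 30,
                    question = 10, monologue = 20)

#' Build prosody trajectories for a speech task
#'
#' Returns the ground-truth generators for one synthetic recording: an f0
#' trajectory (Hz), an intensity trajectory (dB, uncalibrated Praat-style
#' reference where a full-scale sine sits at 91 dB), and a voicing indicator.
#' Tones are flat, legatos glide between two pitches, VCVs have an unvoiced
#' gap, and the connected-speech tasks (phrase, passage, question, monologue)
#' are built from voiced spans with declination and slow modulation,
#' separated by pauses.
#'
#' @param task_type one of `r paste(TASK_TYPES, collapse = ", ")`.
#' @param duration_s recording length in seconds.
#' @param seed integer seed controlling the random modulation.
#' @param f0_base speaker's habitual pitch in Hz (default 120).
#' @param intensity_base habitual intensity in dB (default 65).
#' @return a list with functions `f0(t)`, `intensity(t)`, `voicing(t)`.
#' @export
task_trajectories <- function(task_type, duration_s, seed,
                              f0_base = 120, intensity_base = 65) {
  task_type <- match.arg(task_type, TASK_TYPES)
  with_seed(derive_seed(seed, paste0("traj-", task_type)), {
    edge <- 0.2  # unvoiced lead-in / lead-out (s)
    if (task_type == "tone") {
      st_off <- sample(c(-5, 0, 5), 1)
      f0c <- f0_base * 2^(st_off / 12)
      dbc <- intensity_base + sample(c(-6, 0, 6), 1)
      f0 <- function(t) rep(f0c, length(t))
      inten <- function(t) rep(dbc, length(t))
      voic <- function(t) t > edge & t < duration_s - edge
    } else if (task_type == "legato") {
      st0 <- runif(1, -4, 0); st1 <- st0 + sample(c(-7, 7), 1)
      f0 <- function(t) {
        u <- pmin(pmax((t - edge) / max(duration_s - 2 * edge, 1e-9), 0), 1)
        f0_base * 2^((st0 + (st1 - st0) * u) / 12)
      }
      inten <- function(t) rep(intensity_base, length(t))
      voic <- function(t) t > edge & t < duration_s - edge
    } else if (task_type == "vcv") {
      gap0 <- duration_s * 0.45; gap1 <- duration_s * 0.55
      stress <- sample(c(0, 2), 1)
      f0 <- function(t)
        f0_base * 2^((stress * (t < gap0) - 1) / 12)
      inten <- function(t)
        intensity_base + 3 * (t < gap0) * (stress > 0)
      voic <- function(t)
        (t > edge & t < gap0) | (t > gap1 & t < duration_s - edge)
    } else {
      # connected speech: voiced spans separated by pauses
      spans <- list(); t0 <- edge
      while (t0 < duration_s - edge) {
        len <- runif(1, 0.4, 2.0)
        spans[[length(spans) + 1L]] <- c(t0, min(t0 + len, duration_s - edge))
        t0 <- t0 + len + runif(1, 0.1, 0.45)
      }
      spans <- do.call(rbind, spans)
      # slow f0 modulation: per-span declination plus a sinusoid
      ph <- runif(1, 0, 2 * pi); rate <- runif(1, 0.3, 0.8)
      amp <- runif(1, 1.5, 3.5)           # ST
      iamp <- runif(1, 3, 6)              # dB
      iph <- runif(1, 0, 2 * pi)
      span_start <- function(t) {
        idx <- vapply(t, function(ti) {
          k <- which(spans[, 1] <= ti & ti <= spans[, 2])
          if (length(k)) spans[k[1], 1] else NA_real_
        }, numeric(1))
        idx
      }
      f0 <- function(t) {
        s0 <- span_start(t)
        decl <- ifelse(is.na(s0), 0, -1.5 * (t - s0))  # ST/s declination
        f0_base * 2^((amp * sin(2 * pi * rate * t + ph) + decl) / 12)
      }
      inten <- function(t)
        intensity_base + iamp * 0.5 * sin(2 * pi * rate * t + iph) +
          iamp * 0.5 * sin(2 * pi * 0.13 * t)
      voic <- function(t) {
        vapply(t, function(ti)
          any(spans[, 1] <= ti & ti <= spans[, 2]), logical(1))
      }
    }
    list(f0 = f0, intensity = inten, voicing = voic)
  })
}

#' Configuration for one synthetic session
#'
#' Defaults mirror the acquisition setting: 8 sEMG channels at 2222 Hz
#' band-limited to 20-450 Hz, audio at 44.1 kHz, f0 confined to
#' \[65, 475\] Hz. Coupling gains map (f0 deviation in ST, intensity
#' deviation in dB, voicing) to each channel's activation envelope through a
#' softplus link; they are drawn once from the seed unless supplied.
#'
#' @param seed integer; the only source of randomness.
#' @param task_type speech task label (one of the seven task types).
#' @param duration_s recording length (default: task-typical duration).
#' @param trajectories optional list as returned by [task_trajectories()].
#' @param n_channels number of sEMG channels (default 8).
#' @param fs_emg sEMG sampling rate in Hz (default 2222).
#' @param fs_audio audio sampling rate in Hz (default 44100).
#' @param coupling_gains optional `n_channels x 4` matrix (intercept, f0, dB,
#'   voicing columns).
#' @param emg_noise_floor additive noise floor as a fraction of the peak
#'   activation envelope (default 0.05).
#' @param audio_snr_db audio signal-to-noise ratio in dB (default 30).
#' @param f0_base,intensity_base habitual pitch (Hz) / loudness (dB).
#' @param calibration_offset_db known SPL-meter minus recorded-level offset
#'   carried in the session for calibration tests (default 12).
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(seed, task_type = "phrase", duration_s = NULL,
                         trajectories = NULL, n_channels = 8L,
                         fs_emg = 2222, fs_audio = 44100,
                         coupling_gains = NULL, emg_noise_floor = 0.05,
                         audio_snr_db = 30, f0_base = 120,
                         intensity_base = 65, calibration_offset_db = 12) {
  task_type <- match.arg(task_type, TASK_TYPES)
  duration_s <- duration_s %||% unname(TASK_DURATIONS[task_type])
  stopifnot(duration_s > 0, n_channels >= 1L, fs_emg < fs_audio)
  if (is.null(trajectories))
    trajectories <- task_trajectories(task_type, duration_s, seed,
                                      f0_base, intensity_base)
  if (is.null(coupling_gains)) {
    coupling_gains <- with_seed(derive_seed(seed, "gains"), {
      # f0 gains sized so that the f0-induced envelope modulation clears the
      # short-frame RMS estimation noise (~17% over 40 ms at 2222 Hz):
      # d log(env)/dST = gain * sigmoid factor (~0.5) must exceed ~0.12
      cbind(intercept = runif(n_channels, -0.8, -0.2),
            f0_st = runif(n_channels, 0.22, 0.40) *
              sample(c(-1, 1), n_channels, replace = TRUE),
            int_db = runif(n_channels, 0.08, 0.18),
            voicing = runif(n_channels, 0.8, 1.6))
    })
  }
  stopifnot(nrow(coupling_gains) == n_channels, ncol(coupling_gains) == 4L)
  structure(list(seed = as.integer(seed), task_type = task_type,
                 duration_s = duration_s, trajectories = trajectories,
                 n_channels = as.integer(n_channels), fs_emg = fs_emg,
                 fs_audio = fs_audio, coupling_gains = coupling_gains,
                 emg_noise_floor = emg_noise_floor,
                 audio_snr_db = audio_snr_db, f0_base = f0_base,
                 intensity_base = intensity_base,
                 calibration_offset_db = calibration_offset_db),
            class = "synth_config")
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

#' Synthesize a voiced source waveform from an f0 contour
#'
#' Impulse excitation at the instantaneous period (phase accumulated by
#' integrating f0) shaped by a two-pole resonator near 500 Hz — enough
#' harmonic structure for an autocorrelation pitch tracker, without a full
#' vocal-tract model. Spans where the contour is undefined are silent.
#'
#' @param f0_contour a `contour` in Hz (defined values within \[20, 1000\]).
#' @param fs_audio output sampling rate (Hz).
#' @param seed integer seed (randomizes the initial phase only).
#' @return a `signal_track` at `fs_audio`.
#' @export
glottal_source <- function(f0_contour, fs_audio, seed = 1L) {
  stopifnot(inherits(f0_contour, "contour"))
  vals <- f0_contour$values
  if (any(!is.na(vals) & (vals < 20 | vals > 1000)))
    stopf("glottal_source: f0 outside [20, 1000] Hz")
  dur <- max(f0_contour$times) + (if (length(f0_contour$times) > 1)
    f0_contour$times[2] - f0_contour$times[1] else 0)
  n <- max(1L, round(dur * fs_audio))
  t <- (seq_len(n) - 1) / fs_audio
  f0 <- contour_at(f0_contour, t)
  voiced <- !is.na(f0)
  x <- numeric(n)
  if (any(voiced)) {
    f0v <- ifelse(voiced, f0, 0)
    phase0 <- with_seed(derive_seed(seed, "phase"), runif(1, 0, 1))
    phase <- phase0 + cumsum(f0v) / fs_audio
    pulse <- c(0, diff(floor(phase)) >= 1) * voiced
    # two-pole resonator: centre 500 Hz, bandwidth 150 Hz
    r <- exp(-pi * 150 / fs_audio)
    th <- 2 * pi * 500 / fs_audio
    y <- stats::filter(pulse, c(2 * r * cos(th), -r * r), method = "recursive")
    x <- as.numeric(y)
    x[!voiced] <- 0
  }
  signal_track(x, fs_audio, units = "source amplitude")
}

# zero-phase band-pass via FFT with raised-cosine transitions
fft_bandpass <- function(x, fs, f_lo = 20, f_hi = 450, trans = 10) {
  n <- length(x)
  X <- fft(x)
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)    # two-sided frequency magnitude
  ramp <- function(f, a, b) pmin(pmax((f - a) / (b - a), 0), 1)
  mask <- ramp(f, f_lo - trans, f_lo) * (1 - ramp(f, f_hi, f_hi + trans))
  Re(fft(X * mask, inverse = TRUE)) / n
}

#' Synthesize one sEMG channel from an activation envelope
#'
#' Amplitude-modulated interference pattern: Gaussian noise band-passed to
#' 20-450 Hz, multiplied by the (nonnegative) activation envelope, plus an
#' additive band-limited noise floor. Short-time RMS is monotone in the
#' activation.
#'
#' @param activation a `contour` of nonnegative activation (a.u.).
#' @param fs_emg sampling rate (Hz).
#' @param noise_floor additive floor as a fraction of the peak envelope.
#' @param seed integer seed.
#' @return a `signal_track` at `fs_emg`.
#' @export
emg_from_activation <- function(activation, fs_emg, noise_floor = 0.05,
                                seed = 1L) {
  stopifnot(inherits(activation, "contour"))
  av <- activation$values
  if (any(is.na(av)) || any(av < 0))
    stopf("emg_from_activation: activation must be defined and >= 0")
  dur <- max(activation$times) + (if (length(activation$times) > 1)
    activation$times[2] - activation$times[1] else 0)
  n <- max(1L, round(dur * fs_emg))
  t <- (seq_len(n) - 1) / fs_emg
  env <- approx(activation$times, av, xout = t, rule = 2)$y
  with_seed(derive_seed(seed, "emg"), {
    carrier <- fft_bandpass(rnorm(n), fs_emg)
    floor_n <- if (noise_floor > 0)
      fft_bandpass(rnorm(n), fs_emg) * noise_floor * max(env) else 0
    signal_track(carrier * env + floor_n, fs_emg, units = "a.u. (sEMG)")
  })
}

#' Generate a complete synthetic session
#'
#' Audio (voiced source scaled to the intensity trajectory plus noise at the
#' configured SNR), `n_channels` coupled sEMG tracks, ground-truth f0 and
#' intensity contours, and the task label. Bit-identical under an identical
#' config.
#'
#' @param config a [synth_config()].
#' @return an object of class `synth_session` with elements `audio`, `emg`
#'   (list of `signal_track`), `truth_f0` (Hz contour, `NA` when unvoiced),
#'   `truth_intensity` (dB contour), `task_label`, `calibration_offset_db`,
#'   and `config`.
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  step <- 0.005
  times <- seq(0, config$duration_s - step, by = step)
  voic <- config$trajectories$voicing(times)
  f0v <- pmin(pmax(config$trajectories$f0(times), 65), 475)
  # unvoiced spans are silent: their intensity sits 30 dB below the
  # habitual level, not at the trajectory value
  intenv <- ifelse(voic, config$trajectories$intensity(times),
                   config$intensity_base - 30)
  truth_f0 <- contour(times, ifelse(voic, f0v, NA_real_), "Hz")
  truth_int <- contour(times, intenv, "dB")

  src <- glottal_source(truth_f0, config$fs_audio,
                        derive_seed(config$seed, "source"))
  n <- length(src$samples)
  ta <- (seq_len(n) - 1) / config$fs_audio
  # impose the intensity trajectory: normalize the source's smoothed RMS
  # envelope, then scale to the target rms 10^((I - 91)/20) * sqrt(1/2)
  env <- sqrt(pmax(smooth_ma(src$samples^2, round(0.05 * config$fs_audio)),
                   0))
  env[env < 1e-8 * max(env, 1e-12)] <- Inf   # silent spans stay silent
  target_rms <- sqrt(4e-10 * 10^(approx(times, intenv, xout = ta,
                                        rule = 2)$y / 10))
  audio <- src$samples / env * target_rms
  audio[!is.finite(audio)] <- 0
  sig_rms <- sqrt(mean(audio[audio != 0]^2))
  noise <- with_seed(derive_seed(config$seed, "anoise"),
                     rnorm(n, sd = max(sig_rms, 1e-12) *
                             10^(-config$audio_snr_db / 20)))
  audio <- signal_track(audio + noise, config$fs_audio,
                        units = "normalized amplitude")

  # per-channel activation envelopes from the prosody state; pitch deviation
  # is referenced to the speaker's habitual f0 so that constant-pitch tasks
  # still carry pitch information across sessions
  f0_st <- ifelse(voic, 12 * log2(f0v / config$f0_base), 0)
  int_dev <- intenv - mean(intenv)
  emg <- vector("list", config$n_channels)
  for (ch in seq_len(config$n_channels)) {
    g <- config$coupling_gains[ch, ]
    act <- softplus(g[1] + g[2] * f0_st + g[3] * int_dev + g[4] * voic)
    emg[[ch]] <- emg_from_activation(
      contour(times, act, "a.u."), config$fs_emg, config$emg_noise_floor,
      derive_seed(config$seed, paste0("emg-ch", ch)))
    emg[[ch]]$channel <- sprintf("ch%d", ch)
  }

  structure(list(audio = audio, emg = emg, truth_f0 = truth_f0,
                 truth_intensity = truth_int, task_label = config$task_type,
                 calibration_offset_db = config$calibration_offset_db,
                 config = config),
            class = "synth_session")
}

#' @export
print.synth_session <- function(x, ...) {
  cat(sprintf(
    "<synth_session> task=%s, %.1f s audio @ %g Hz, %d sEMG channels @ %g Hz\n",
    x$task_label, track_duration(x$audio), x$audio$rate, length(x$emg),
    x$emg[[1]]$rate))
  invisible(x)
}

# centred moving average via cumulative sums (reflective edges)
smooth_ma <- function(x, w) {
  w <- max(1L, as.integer(w))
  if (w %% 2L == 0L) w <- w + 1L
  h <- w %/% 2L
  xp <- c(rev(x[seq_len(h)]), x, rev(x[length(x) - seq_len(h) + 1L]))
  cs <- c(0, cumsum(xp))
  (cs[(w + 1):(length(xp) + 1)] - cs[seq_len(length(xp) - w + 1)]) / w
}

#' Write a session to disk in plain formats
#'
#' Audio as 32-bit float WAV, EMG as a delimited multi-column table, truth
#' contours as delimited text, and a JSON metadata sidecar (rates, channel
#' names, task label, calibration offset, coupling gains).
#'
#' @param session a `synth_session`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_wav(session$audio, file.path(dir, "audio.wav"), bits = 32L)
  emg <- do.call(cbind, lapply(session$emg, `[[`, "samples"))
  colnames(emg) <- vapply(session$emg, `[[`, "", "channel")
  write.table(format(emg, digits = 9, trim = TRUE, scientific = TRUE),
              file.path(dir, "emg.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_contour(session$truth_f0, file.path(dir, "truth_f0.tsv"))
  write_contour(session$truth_intensity, file.path(dir, "truth_intensity.tsv"))
  meta <- list(task_label = session$task_label,
               fs_audio = session$audio$rate, fs_emg = session$emg[[1]]$rate,
               n_channels = length(session$emg),
               channels = colnames(emg),
               calibration_offset_db = session$calibration_offset_db,
               coupling_gains = unclass(session$config$coupling_gains),
               seed = session$config$seed)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a session written by [write_session()]
#' @param dir session directory.
#' @return a `synth_session` (without the generating `config`).
#' @export
read_session <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  audio <- read_wav(file.path(dir, "audio.wav"))
  emg_tab <- read.table(file.path(dir, "emg.tsv"), header = TRUE, sep = "\t")
  emg <- lapply(seq_len(ncol(emg_tab)), function(ch) {
    tr <- signal_track(emg_tab[[ch]], meta$fs_emg, units = "a.u. (sEMG)",
                       channel = names(emg_tab)[ch])
    tr
  })
  structure(list(audio = audio, emg = emg,
                 truth_f0 = read_contour(file.path(dir, "truth_f0.tsv")),
                 truth_intensity =
                   read_contour(file.path(dir, "truth_intensity.tsv")),
                 task_label = meta$task_label,
                 calibration_offset_db = meta$calibration_offset_db,
                 config = NULL),
            class = "synth_session")
}
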