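# Shared fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# constant-f0 pulse train with additive noise at a given SNR
make_pulse_train <- function(f0, duration_s = 1, fs = 44100, snr_db = 30,
                             seed = 1L) {
  step <- 0.005
  times <- seq(0, duration_s - step, by = step)
  cont <- contour(times, rep(f0, length(times)), "Hz")
  src <- glottal_source(cont, fs, seed)
  x <- src$samples / max(abs(src$samples))
  noise <- with_seed_local(seed + 7L, rnorm(length(x)))
  x <- x + noise * sqrt(mean(x^2)) * 10^(-snr_db / 20)
  signal_track(x, fs)
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# a small phrase session reused by several files
phrase_session <- function()
  cached("phrase10", generate_session(synth_config(11, task_type = "phrase",
                                                   duration_s = 10)))

# random band-limited frames for fuzz checks (samples x n matrix)
random_frames <- function(n_frames, frame_len = 89L, fs = 2222, seed = 5L) {
  with_seed_local(seed, {
    x <- rnorm(n_frames * frame_len + 200L)
    # crude band-limit: difference then moving average
    x <- stats::filter(x, rep(1 / 3, 3), sides = 2)
    x[is.na(x)] <- 0
    matrix(x[seq_len(n_frames * frame_len)], frame_len)
  })
}
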