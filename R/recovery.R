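# The end-to-end parameter-recovery suite: a fixed single-speaker session
# mix (>= 10 minutes of signal across the seven task types), processed by
# the full chain (align -> targets -> features -> split/augment/PCA ->
# train -> predict). Used by the acceptance test and the acceptance report.

RECOVERY_TASKS <- data.frame(
  task = c("tone", "tone", "legato", "legato", "vcv", "vcv",
           "phrase", "phrase", "phrase", "question", "question",
           "passage", "passage", "passage", "monologue", "monologue"),
  duration_s = c(15, 15, 20, 20, 15, 15, 50, 50, 45, 40, 40, 60, 60, 60,
                 50, 50),
  stringsAsFactors = FALSE)

#' Generate the fixed recovery-suite sessions
#'
#' One synthetic speaker: a fixed task mix spanning all seven task types
#' and summing to over 10 minutes of signal, with per-session seeds derived
#' from the master seed.
#'
#' @param seed master seed.
#' @return list of `synth_session`s.
#' @export
recovery_suite_sessions <- function(seed) {
  # one speaker = one coupling physiology: the gain matrix is drawn once
  # from the master seed and shared by every session in the suite
  gains <- synth_config(derive_seed(seed, "speaker"))$coupling_gains
  lapply(seq_len(nrow(RECOVERY_TASKS)), function(i)
    generate_session(synth_config(
      derive_seed(seed, paste0("recovery", i)),
      task_type = RECOVERY_TASKS$task[i],
      duration_s = RECOVERY_TASKS$duration_s[i],
      coupling_gains = gains)))
}

#' Run the end-to-end recovery experiment
#'
#' Generates (or receives) the suite, aligns each session once, builds the
#' f0 and intensity datasets, and runs the single-speaker scheme for each
#' stream. The default network is reduced (hidden 64-32, 40 epochs) so
#' the full chain fits a single-CPU test budget; the headline property is
#' recovery (held-out CCC), not capacity.
#'
#' @param seed master seed for generation, splitting, augmentation and
#'   training.
#' @param sessions optional pre-generated session list.
#' @param hidden_layers,max_epochs,patience,batch_size model overrides.
#' @param verbose print progress.
#' @return list with elements `f0` and `intensity` (each an
#'   `experiment_result`) plus `n_signal_seconds`.
#' @export
run_recovery_suite <- function(seed, sessions = NULL,
                               hidden_layers = c(64L, 32L),
                               max_epochs = 40L, patience = 12L,
                               batch_size = 1024L, verbose = FALSE) {
  # stream sessions one at a time: a session's audio plus its warped
  # 44.1-kHz EMG tracks are large, and holding the whole suite at once
  # does not fit an 8-GiB budget
  gains <- synth_config(derive_seed(seed, "speaker"))$coupling_gains
  n_sessions <- if (is.null(sessions)) nrow(RECOVERY_TASKS)
                else length(sessions)
  parts <- list(f0 = list(), intensity = list())
  secs <- 0
  for (i in seq_len(n_sessions)) {
    s <- if (is.null(sessions))
      generate_session(synth_config(
        derive_seed(seed, paste0("recovery", i)),
        task_type = RECOVERY_TASKS$task[i],
        duration_s = RECOVERY_TASKS$duration_s[i],
        coupling_gains = gains))
    else sessions[[i]]
    secs <- secs + track_duration(s$audio)
    if (verbose) message(sprintf("processing session %d/%d (%s)", i,
                                 n_sessions, s$task_label))
    al <- align_emg_to_audio(s)
    for (stream in c("f0", "intensity"))
      parts[[stream]][[i]] <- process_session(s, stream, aligned = al)
    rm(s, al)
  }
  out <- list(n_signal_seconds = secs)
  for (stream in c("f0", "intensity")) {
    ps <- parts[[stream]]
    x <- do.call(rbind, lapply(ps, function(p) p$features$values))
    y <- unlist(lapply(ps, `[[`, "targets"))
    labels <- unlist(lapply(ps, `[[`, "labels"))
    ft <- unlist(lapply(ps, `[[`, "frame_times"))
    keep <- !is.na(y) & apply(is.finite(x), 1, all)
    ds <- list(x = x[keep, , drop = FALSE], y = y[keep],
               labels = labels[keep], unit = ps[[1]]$unit,
               frame_times = ft[keep])
    parts[[stream]] <- list()
    if (verbose) message(sprintf("%s: %d frames x %d features", stream,
                                 nrow(ds$x), ncol(ds$x)))
    out[[stream]] <- run_experiment(
      ds, paste0("single_", stream), seed,
      hidden_layers = hidden_layers, max_epochs = max_epochs,
      patience = patience, batch_size = batch_size, verbose = verbose)
    rm(ds)
  }
  out
}
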