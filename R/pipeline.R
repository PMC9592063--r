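# End-to-end orchestration: per-session processing (align -> targets ->
# features), dataset assembly across sessions, fold-wise training with
# in-fold PCA/augmentation, evaluation, and the staged on-disk pipeline
# behind the `emg2prosody` command line.

#' Frame specifications of the two target streams
#'
#' 40 ms / 20 ms for f0; 150 ms / 30 ms for intensity.
#' @param stream `"f0"` or `"intensity"`.
#' @return a [frame_spec()].
#' @export
stream_frame_spec <- function(stream) {
  switch(match.arg(stream, c("f0", "intensity")),
         f0 = frame_spec(0.040, 0.020),
         intensity = frame_spec(0.150, 0.030))
}

# downsample a track by linear interpolation (content is band-limited well
# below the target Nyquist, so this is adequate)
resample_track <- function(track, fs_out) {
  n_out <- floor(track_duration(track) * fs_out)
  t_out <- (seq_len(n_out) - 1) / fs_out
  signal_track(approx((seq_along(track$samples) - 1) / track$rate,
                      track$samples, xout = t_out, rule = 2)$y,
               fs_out, units = track$units, channel = track$channel)
}

#' Process one session into paired frames for one stream
#'
#' Runs alignment (unless supplied), extracts the stream's acoustic target
#' (f0 contour via [extract_f0()] or SPL-calibrated intensity via
#' [extract_intensity()]), frames targets and warped sEMG on the shared
#' `k * step` grid, and truncates both to the common frame count.
#'
#' @param session a `synth_session`.
#' @param stream `"f0"` or `"intensity"`.
#' @param pitch a [pitch_params()].
#' @param aligned optional result of [align_emg_to_audio()] to reuse across
#'   streams.
#' @param fs_feat rate the warped sEMG is brought back to for feature
#'   extraction (default 2222).
#' @return list with `features` (`feature_matrix`), `targets` (numeric,
#'   `NA` where undefined), `frame_times`, `labels` (task label per frame),
#'   `unit`.
#' @export
process_session <- function(session, stream, pitch = pitch_params(),
                            aligned = NULL, fs_feat = 2222) {
  stream <- match.arg(stream, c("f0", "intensity"))
  spec <- stream_frame_spec(stream)
  if (is.null(aligned)) aligned <- align_emg_to_audio(session)
  emg <- lapply(aligned$warped, resample_track, fs_out = fs_feat)
  fm <- extract_emg_features(emg, spec)
  if (stream == "f0") {
    cont <- extract_f0(session$audio, pitch)
    unit <- "Hz"
  } else {
    cont <- extract_intensity(session$audio, f_min = pitch$f_min)
    cal <- calibration_info(session$calibration_offset_db, 0)
    cont <- calibrate_spl(cont, cal)
    unit <- "dB SPL"
  }
  tg <- frame_targets(cont, spec$frame_len, spec$step)
  nf <- min(nrow(fm$values), length(tg$values))
  fm$values <- fm$values[seq_len(nf), , drop = FALSE]
  fm$frame_times <- fm$frame_times[seq_len(nf)]
  fm$frame_centers <- fm$frame_centers[seq_len(nf)]
  list(features = fm, targets = tg$values[seq_len(nf)],
       frame_times = fm$frame_times,
       labels = rep(session$task_label, nf), unit = unit)
}

#' Assemble a multi-session dataset for one stream
#'
#' Concatenates per-session frames, dropping frames with undefined targets
#' (f0 exists only during voiced speech).
#'
#' @param sessions list of `synth_session`s.
#' @param stream `"f0"` or `"intensity"`.
#' @param pitch a [pitch_params()].
#' @param aligned_list optional list of precomputed alignments.
#' @return list with `x` (frames x features), `y` (targets in `unit`),
#'   `labels`, `unit`, `session_id`, `frame_times`.
#' @export
build_dataset <- function(sessions, stream, pitch = pitch_params(),
                          aligned_list = NULL) {
  parts <- lapply(seq_along(sessions), function(i)
    process_session(sessions[[i]], stream, pitch,
                    aligned = if (is.null(aligned_list)) NULL
                              else aligned_list[[i]]))
  x <- do.call(rbind, lapply(parts, function(p) p$features$values))
  y <- unlist(lapply(parts, `[[`, "targets"))
  labels <- unlist(lapply(parts, `[[`, "labels"))
  sid <- rep(seq_along(parts),
             vapply(parts, function(p) length(p$targets), 0L))
  ft <- unlist(lapply(parts, `[[`, "frame_times"))
  keep <- !is.na(y) & apply(is.finite(x), 1, all)
  list(x = x[keep, , drop = FALSE], y = y[keep], labels = labels[keep],
       unit = parts[[1]]$unit, session_id = sid[keep],
       frame_times = ft[keep])
}

#' Train and evaluate one scheme over 5 folds
#'
#' For each fold: augmentation and PCA are fit on that fold's training
#' portion only, the network is trained with early stopping on the fold's
#' validation set, and train/validation metrics are computed. The final
#' fold is the one with the highest validation CCC; its model is evaluated
#' once on the held-out test set. f0 metrics other than MAPE are computed
#' in ST (speaker-relative); MAPE on the Hz scale. Intensity metrics in
#' dB SPL.
#'
#' @param dataset a [build_dataset()] result.
#' @param scheme a scheme name (see [model_config()]).
#' @param seed master seed.
#' @param pca_variance PCA explained-variance target (default 0.90).
#' @param augment_scale augmentation noise scale (default 0.1).
#' @param hidden_layers,max_epochs,patience,batch_size optional model
#'   overrides (defaults per scheme).
#' @param verbose print progress.
#' @return list of class `experiment_result`: `fold_reports` (train and
#'   validation `eval_report`s per fold), `final_fold`, `test_report`,
#'   `test_report_native` (Hz/dB SPL scale), `models`, `split`, `stats`,
#'   `pca_components` (per fold), `overlay` (test frame times, observed,
#'   predicted in native units).
#' @export
run_experiment <- function(dataset, scheme, seed, pca_variance = 0.90,
                           augment_scale = 0.1, hidden_layers = NULL,
                           max_epochs = NULL, patience = NULL,
                           batch_size = NULL, verbose = FALSE) {
  is_f0 <- grepl("_f0$", scheme)
  stats <- if (is_f0) speaker_stats(f0_hz = dataset$y)
           else speaker_stats(intensity_db = dataset$y)
  cfg0 <- model_config(scheme, input_dim = 1L, seed = seed)
  y_t <- transform_targets(dataset$y, cfg0$target_transform, stats)
  unit_t <- if (is_f0) "ST" else if (cfg0$target_transform ==
                                       "spl_normalized_0_1") "0-1" else "dB SPL"

  split <- stratified_split(dataset$labels, seed)
  folds <- make_folds(split)
  fold_reports <- vector("list", split$k)
  models <- vector("list", split$k)
  pca_components <- integer(split$k)
  for (f in seq_len(split$k)) {
    tr <- folds[[f]]$train; va <- folds[[f]]$validation
    aug <- augment_gaussian(dataset$x[tr, , drop = FALSE], y_t[tr],
                            scale = augment_scale,
                            seed = derive_seed(seed, paste0("aug", f)))
    pca <- fit_pca(aug$x, pca_variance)
    pca_components[f] <- pca$n_components
    xs_tr <- apply_pca(pca, aug$x)
    xs_va <- apply_pca(pca, dataset$x[va, , drop = FALSE])
    cfg <- model_config(scheme, input_dim = pca$n_components,
                        hidden_layers = hidden_layers,
                        batch_size = batch_size,
                        max_epochs = max_epochs %||% 500L,
                        patience = patience %||% 20L,
                        seed = derive_seed(seed, paste0("fold", f)))
    mdl <- train_model(cfg, xs_tr, aug$y, xs_va, y_t[va], stats = stats,
                       verbose = verbose)
    mdl$pca <- pca
    models[[f]] <- mdl
    pr_tr <- predict(mdl, apply_pca(pca, dataset$x[tr, , drop = FALSE]),
                     transformed = TRUE)
    pr_va <- predict(mdl, xs_va, transformed = TRUE)
    fold_reports[[f]] <- list(
      train = compute_metrics(y_t[tr], pr_tr, unit = unit_t,
                              dataset_tag = "train"),
      validation = compute_metrics(y_t[va], pr_va, unit = unit_t,
                                   dataset_tag = "validation"))
    if (verbose)
      message(sprintf("fold %d: %d PCs, val CCC %.3f", f,
                      pca$n_components, fold_reports[[f]]$validation$ccc))
  }
  final <- select_final_fold(lapply(fold_reports, `[[`, "validation"))
  mdl <- models[[final]]
  te <- split$test
  xs_te <- apply_pca(mdl$pca, dataset$x[te, , drop = FALSE])
  pred_t <- predict(mdl, xs_te, transformed = TRUE)
  pred_native <- predict(mdl, xs_te)
  test_report <- compute_metrics(y_t[te], pred_t, unit = unit_t,
                                 dataset_tag = "test")
  test_native <- compute_metrics(dataset$y[te], pred_native,
                                 unit = dataset$unit, dataset_tag = "test")
  structure(list(fold_reports = fold_reports, final_fold = final,
                 test_report = test_report, test_report_native = test_native,
                 models = models, split = split, stats = stats,
                 pca_components = pca_components,
                 overlay = data.frame(time_s = dataset$frame_times[te],
                                      observed = dataset$y[te],
                                      predicted = pred_native)),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> final fold %d of %d\n", x$final_fold,
              length(x$fold_reports)))
  print(x$test_report)
  invisible(x)
}

# ---- staged disk pipeline -------------------------------------------------

PIPELINE_STAGES <- c("simulate", "align", "targets", "features", "prep",
                     "train", "evaluate", "predict")

#' Read an experiment configuration (JSON)
#'
#' Fields: `seed` (mandatory), `out_dir`, `sessions` (list of
#' `{task, duration_s}`; seeds are derived), `streams`, `pitch` overrides,
#' `pca_variance`, `augment_scale`, `model` overrides (`hidden_layers`,
#' `max_epochs`, `patience`, `batch_size`), `scheme_family` (`single` or
#' `multi`).
#'
#' @param path JSON config file.
#' @return a list of class `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$seed)) stopf("config: 'seed' is mandatory")
  defaults <- list(out_dir = "emg2prosody_run",
                   streams = c("f0", "intensity"),
                   scheme_family = "single", pca_variance = 0.90,
                   augment_scale = 0.1, model = list())
  cfg <- modifyList(defaults, cfg)
  if (is.null(cfg$sessions))
    cfg$sessions <- data.frame(task = c("tone", "legato", "phrase"),
                               duration_s = c(4, 5, 10))
  class(cfg) <- "experiment_config"
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(dir, stage, cfg, extra = list()) {
  m <- c(list(stage = stage, seed = cfg$seed, config_hash = config_hash(cfg)),
         extra)
  jsonlite::write_json(m, file.path(dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

load_sessions <- function(cfg) {
  sdirs <- list.dirs(file.path(cfg$out_dir, "sessions"), recursive = FALSE)
  if (!length(sdirs))
    stopf("no session outputs found; run the 'simulate' stage first")
  lapply(sort(sdirs), read_session)
}

#' Run one pipeline stage
#'
#' Stages (in order): `simulate` (write synthetic sessions), `align`
#' (warp paths + aligned EMG), `targets` (framed f0/intensity targets),
#' `features` (per-stream feature matrices), `prep` (stratified split
#' indices), `train`+`evaluate` (fold-wise training, fold summary, final
#' test metrics and overlay), `predict` (final-model predictions for a
#' feature matrix). Each stage writes a manifest with the config hash and
#' seed; reruns with the same config are byte-identical.
#'
#' @param stage stage name.
#' @param cfg an `experiment_config` (or path to one).
#' @return the stage's primary output directory, invisibly.
#' @export
run_stage <- function(stage, cfg) {
  stage <- match.arg(stage, PIPELINE_STAGES)
  if (is.character(cfg)) cfg <- read_experiment_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  pitch <- do.call(pitch_params, cfg$pitch %||% list())
  sessions_dir <- file.path(cfg$out_dir, "sessions")

  if (stage == "simulate") {
    tasks <- as.data.frame(cfg$sessions)
    for (i in seq_len(nrow(tasks))) {
      sc <- synth_config(derive_seed(cfg$seed, paste0("session", i)),
                         task_type = tasks$task[i],
                         duration_s = tasks$duration_s[i])
      write_session(generate_session(sc),
                    file.path(sessions_dir, sprintf("s%03d", i)))
    }
    write_manifest(cfg$out_dir, stage, cfg,
                   list(n_sessions = nrow(tasks)))
  } else if (stage == "align") {
    sessions <- load_sessions(cfg)
    for (i in seq_along(sessions)) {
      al <- align_emg_to_audio(sessions[[i]])
      sd <- file.path(sessions_dir, sprintf("s%03d", i))
      for (ch in seq_along(al$paths))
        write_warp_path(al$paths[[ch]],
                        file.path(sd, sprintf("warp_ch%d.tsv", ch)))
      warped <- lapply(al$warped, resample_track, fs_out = 2222)
      tab <- do.call(cbind, lapply(warped, `[[`, "samples"))
      colnames(tab) <- sprintf("ch%d", seq_along(warped))
      write.table(format(tab, digits = 9, trim = TRUE),
                  file.path(sd, "emg_aligned.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    write_manifest(cfg$out_dir, stage, cfg,
                   list(n_sessions = length(sessions)))
  } else if (stage == "targets") {
    sessions <- load_sessions(cfg)
    for (i in seq_along(sessions)) {
      s <- sessions[[i]]
      sd <- file.path(sessions_dir, sprintf("s%03d", i))
      f0 <- extract_f0(s$audio, pitch)
      write_contour(f0, file.path(sd, "f0_contour.tsv"))
      int <- calibrate_spl(extract_intensity(s$audio, f_min = pitch$f_min),
                           calibration_info(s$calibration_offset_db, 0))
      write_contour(int, file.path(sd, "intensity_contour.tsv"))
      for (stream in cfg$streams) {
        spec <- stream_frame_spec(stream)
        tg <- frame_targets(if (stream == "f0") f0 else int,
                            spec$frame_len, spec$step)
        write_contour(tg, file.path(sd, sprintf("targets_%s.tsv", stream)))
      }
    }
    write_manifest(cfg$out_dir, stage, cfg,
                   list(n_sessions = length(sessions)))
  } else if (stage == "features") {
    sessions <- load_sessions(cfg)
    dims <- c()
    for (i in seq_along(sessions)) {
      sd <- file.path(sessions_dir, sprintf("s%03d", i))
      af <- file.path(sd, "emg_aligned.tsv")
      if (!file.exists(af))
        stopf("missing aligned EMG for session %d; run the 'align' stage", i)
      tab <- read.table(af, header = TRUE, sep = "\t")
      emg <- lapply(seq_len(ncol(tab)), function(ch)
        signal_track(tab[[ch]], 2222, channel = names(tab)[ch]))
      for (stream in cfg$streams) {
        fm <- extract_emg_features(emg, stream_frame_spec(stream))
        dims <- unique(c(dims, ncol(fm$values)))
        write_feature_matrix(fm, file.path(sd,
                                           sprintf("features_%s.tsv", stream)))
      }
    }
    write_manifest(cfg$out_dir, stage, cfg,
                   list(n_sessions = length(sessions),
                        feature_dimension = dims))
  } else if (stage %in% c("prep", "train", "evaluate", "predict")) {
    run_model_stages(stage, cfg, pitch)
  }
  invisible(cfg$out_dir)
}

# read per-session on-disk artifacts into a build_dataset()-shaped list
assemble_from_disk <- function(cfg, stream) {
  sessions_dir <- file.path(cfg$out_dir, "sessions")
  sdirs <- sort(list.dirs(sessions_dir, recursive = FALSE))
  xs <- list(); ys <- list(); labs <- list(); ts <- list()
  for (sd in sdirs) {
    ff <- file.path(sd, sprintf("features_%s.tsv", stream))
    tf <- file.path(sd, sprintf("targets_%s.tsv", stream))
    if (!file.exists(ff))
      stopf("missing features in %s; run the 'features' stage", sd)
    if (!file.exists(tf))
      stopf("missing targets in %s; run the 'targets' stage", sd)
    fm <- read_feature_matrix(ff)
    tg <- read_contour(tf)
    meta <- jsonlite::read_json(file.path(sd, "meta.json"),
                                simplifyVector = TRUE)
    nf <- min(nrow(fm$values), length(tg$values))
    xs[[sd]] <- fm$values[seq_len(nf), , drop = FALSE]
    ys[[sd]] <- tg$values[seq_len(nf)]
    labs[[sd]] <- rep(meta$task_label, nf)
    ts[[sd]] <- fm$frame_times[seq_len(nf)]
  }
  x <- do.call(rbind, xs); y <- unlist(ys)
  keep <- !is.na(y) & apply(is.finite(x), 1, all)
  list(x = x[keep, , drop = FALSE], y = y[keep],
       labels = unlist(labs)[keep],
       unit = if (stream == "f0") "Hz" else "dB SPL",
       frame_times = unlist(ts)[keep])
}

run_model_stages <- function(stage, cfg, pitch) {
  for (stream in cfg$streams) {
    ds <- assemble_from_disk(cfg, stream)
    if (stage == "prep") {
      split <- stratified_split(ds$labels, cfg$seed)
      out <- file.path(cfg$out_dir, sprintf("split_%s.tsv", stream))
      idx <- data.frame(
        index = c(split$test, split$trainval),
        partition = c(rep("test", length(split$test)),
                      rep("trainval", length(split$trainval))),
        fold = c(rep(NA_integer_, length(split$test)), split$fold))
      write.table(idx[order(idx$index), ], out, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      write_manifest(cfg$out_dir, "prep", cfg,
                     list(stream = stream, n_frames = length(ds$y),
                          n_test = length(split$test)))
      next
    }
    scheme <- paste0(if (identical(cfg$scheme_family, "multi")) "multi_"
                     else "single_",
                     if (stream == "f0") "f0" else "intensity")
    res <- run_experiment(
      ds, scheme, cfg$seed, pca_variance = cfg$pca_variance,
      augment_scale = cfg$augment_scale,
      hidden_layers = cfg$model$hidden_layers,
      max_epochs = cfg$model$max_epochs,
      patience = cfg$model$patience, batch_size = cfg$model$batch_size)
    if (stage %in% c("train", "evaluate")) {
      summary_tab <- cbind(
        data.frame(dataset = rep(c("train", "validation"),
                                 each = 5)),
        do.call(rbind, c(
          lapply(lapply(res$fold_reports, `[[`, "train"),
                 function(r) as.data.frame(unclass(r)[1:5])),
          lapply(lapply(res$fold_reports, `[[`, "validation"),
                 function(r) as.data.frame(unclass(r)[1:5])))))
      write.table(format(summary_tab, digits = 6),
                  file.path(cfg$out_dir, sprintf("folds_%s.tsv", stream)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write_eval_report(res$test_report_native,
                        file.path(cfg$out_dir,
                                  sprintf("test_%s.json", stream)))
      write.table(format(res$overlay, digits = 8),
                  file.path(cfg$out_dir, sprintf("overlay_%s.tsv", stream)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write_manifest(cfg$out_dir, stage, cfg,
                     list(stream = stream, final_fold = res$final_fold,
                          pca_components = res$pca_components,
                          test_ccc = res$test_report$ccc))
    }
    if (stage == "predict") {
      pred <- res$overlay
      write.table(format(pred, digits = 8),
                  file.path(cfg$out_dir, sprintf("predictions_%s.tsv",
                                                 stream)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write_manifest(cfg$out_dir, stage, cfg, list(stream = stream))
    }
  }
}

#' Human-readable run report
#'
#' Per-fold mean +/- SD of every metric plus the selected final fold's test
#' metrics, per stream.
#'
#' @param run_dir a pipeline output directory after the `evaluate` stage.
#' @return invisibly, a list of per-stream summaries; prints the report.
#' @export
report <- function(run_dir) {
  out <- list()
  for (stream in c("f0", "intensity")) {
    ft <- file.path(run_dir, sprintf("folds_%s.tsv", stream))
    if (!file.exists(ft)) next
    folds <- read.table(ft, header = TRUE, sep = "\t")
    test <- jsonlite::read_json(file.path(run_dir,
                                          sprintf("test_%s.json", stream)),
                                simplifyVector = TRUE)
    cat(sprintf("== %s ==\n", stream))
    for (dsname in c("train", "validation")) {
      d <- folds[folds$dataset == dsname, -1]
      cat(sprintf("  %s (5 folds): %s\n", dsname,
                  paste(sprintf("%s %.3f+/-%.3f", names(d), colMeans(d),
                                apply(d, 2, sd)), collapse = "  ")))
    }
    cat(sprintf(
      "  test: MAPE %.2f%%  r %.3f  CCC %.3f  RMSE %.3f %s  MBE %+.3f %s\n",
      test$mape, test$pearson_r, test$ccc, test$rmse, test$unit, test$mbe,
      test$unit))
    out[[stream]] <- list(folds = folds, test = test)
  }
  invisible(out)
}
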