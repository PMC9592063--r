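# sEMG-to-audio alignment: per-hop envelope features, exact DTW (full-DP
# oracle and linear-memory divide-and-conquer), and per-channel warping of
# the EMG onto the audio timeline.

#' Per-hop envelope features for alignment
#'
#' Summarizes a track per `hop` seconds as log-energy plus four spectral
#' band energies (log), each z-scored per track. Amplitude envelopes are the
#' structure shared between sEMG activity and the acoustic signal, so these
#' features carry the alignment information DTW needs.
#'
#' A light moving average over `smooth_hops` hops suppresses the variance of
#' short-window energy estimates (the sEMG interference pattern is
#' stochastic, so a 10-ms energy estimate is noisy) without blurring the
#' voicing transitions that anchor the alignment.
#'
#' @param track a `signal_track`.
#' @param hop hop length in seconds (default 0.010).
#' @param smooth_hops moving-average width over hops (default 5; 1 disables).
#' @return a matrix with `floor(duration / hop)` rows and 5 columns.
#' @export
envelope_features <- function(track, hop = 0.010, smooth_hops = 5L) {
  stopifnot(inherits(track, "signal_track"), hop > 0)
  fs <- track$rate
  nh <- max(1L, round(hop * fs))
  n_hops <- floor(length(track$samples) / nh)
  if (n_hops < 1L) stopf("envelope_features: track shorter than one hop")
  seg <- matrix(track$samples[seq_len(n_hops * nh)], nrow = nh)
  X <- mvfft(seg)
  n2 <- nh %/% 2L + 1L
  P <- Mod(X[seq_len(n2), , drop = FALSE])^2
  f <- (seq_len(n2) - 1) * fs / nh
  edges <- c(0, 100, 250, 450, fs / 2 + 1)
  feats <- cbind(
    log(colMeans(seg^2) + 1e-30),
    vapply(seq_len(4), function(b) {
      sel <- f >= edges[b] & f < edges[b + 1]
      log(colSums(P[sel, , drop = FALSE]) + 1e-30)
    }, numeric(n_hops)))
  colnames(feats) <- c("logE", paste0("band", 1:4))
  if (smooth_hops > 1L && n_hops > smooth_hops) {
    w <- as.integer(smooth_hops)
    if (w %% 2L == 0L) w <- w + 1L
    h <- w %/% 2L
    feats <- apply(feats, 2, function(v) {
      vp <- c(rev(v[seq_len(h)]), v, rev(v[length(v) - seq_len(h) + 1L]))
      cs <- c(0, cumsum(vp))
      (cs[(w + 1):(length(vp) + 1)] - cs[seq_len(length(vp) - w + 1)]) / w
    })
  }
  # z-score per feature; constant features collapse to zero
  sds <- apply(feats, 2, sd)
  sds[sds < 1e-12] <- 1
  scale(feats, center = TRUE, scale = sds)[, , drop = FALSE]
}

check_warp_path <- function(path, n, m) {
  if (!all(path[1, ] == c(1L, 1L))) return("path must start at (1,1)")
  if (!all(path[nrow(path), ] == c(n, m))) return("path must end at (N,M)")
  d <- diff(path)
  if (any(d < 0) || any(d > 1) || any(rowSums(d) == 0))
    return("path steps must be in {(1,0),(0,1),(1,1)}")
  NULL
}

#' Dynamic time warping (quadratic-memory oracle)
#'
#' Optimal alignment of two feature sequences under Euclidean local cost and
#' steps (1,0), (0,1), (1,1), with a deterministic tie-break (diagonal
#' preferred, then (1,0)). This is the reference implementation; use
#' [dtw_lowmem()] for long sequences.
#'
#' @param a,b numeric matrices (rows = time steps) or vectors.
#' @return a list with `cost`, `path` (two-column 1-based index matrix from
#'   (1,1) to (N,M)), and `workspace_cells` (instrumentation: DP cells
#'   allocated).
#' @export
dtw_full <- function(a, b) {
  a <- as_seq_matrix(a); b <- as_seq_matrix(b)
  res <- .dtw_full_cpp(a, b)
  err <- check_warp_path(res$path, nrow(a), nrow(b))
  if (!is.null(err)) stopf("dtw_full: %s", err)
  res
}

#' Dynamic time warping (exact, linear memory)
#'
#' Divide-and-conquer over the midpoint row: forward and backward cost rows
#' locate a cell the optimal path passes through, and the two halves are
#' solved recursively. Cost is identical to [dtw_full()]; the path may
#' differ only among equal-cost ties. Workspace grows as O(N + M) feature
#' rows instead of O(N x M).
#'
#' @inheritParams dtw_full
#' @return as [dtw_full()].
#' @export
dtw_lowmem <- function(a, b) {
  a <- as_seq_matrix(a); b <- as_seq_matrix(b)
  res <- .dtw_lowmem_cpp(a, b)
  err <- check_warp_path(res$path, nrow(a), nrow(b))
  if (!is.null(err)) stopf("dtw_lowmem: %s", err)
  res
}

as_seq_matrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 1L)
  storage.mode(x) <- "double"
  if (nrow(x) == 0L) stopf("dtw: empty sequence")
  x
}

#' Align all EMG channels of a session to its audio
#'
#' Each channel is upsampled to the audio rate, summarized by
#' [envelope_features()] at the given hop, aligned to the audio features
#' with [dtw_lowmem()], and resampled along the warping path onto the audio
#' timeline (ties collapsed by averaging, linear interpolation between
#' matched hops).
#'
#' A constant-offset dummy feature dimension (difference `step_penalty`)
#' adds an approximately constant cost per path cell, so the alignment does
#' not trade path length for chance level matches between the two
#' modalities: in stretches where the envelopes carry no warping evidence
#' the shortest (diagonal) path wins, while genuine offsets — whose
#' matching gain exceeds the per-cell penalty — are still recovered.
#'
#' @param session a `synth_session` (or any list with `audio` and `emg`).
#' @param hop DTW hop in seconds (default 0.010).
#' @param step_penalty per-cell path-length penalty in z-units (default 2).
#' @return a list with `warped` (list of `signal_track` at the audio rate,
#'   audio duration) and `paths` (list of warp-path matrices).
#' @export
align_emg_to_audio <- function(session, hop = 0.010, step_penalty = 2) {
  audio <- session$audio
  fa <- cbind(envelope_features(audio, hop), step_penalty)
  n_audio <- length(audio$samples)
  out <- list(warped = vector("list", length(session$emg)),
              paths = vector("list", length(session$emg)))
  for (ch in seq_along(session$emg)) {
    tr <- session$emg[[ch]]
    if (track_duration(tr) < hop)
      stopf("align_emg_to_audio: channel %d shorter than one hop", ch)
    # upsample to the audio rate
    t_a <- (seq_len(n_audio) - 1) / audio$rate
    up <- approx((seq_along(tr$samples) - 1) / tr$rate, tr$samples,
                 xout = t_a, rule = 2)$y
    up_tr <- signal_track(up, audio$rate, units = tr$units,
                          channel = tr$channel)
    fe <- cbind(envelope_features(up_tr, hop), 0)
    res <- dtw_lowmem(fe, fa)
    # audio hop -> mean matched EMG hop, then interpolate per audio sample
    agg <- tapply(res$path[, 1], res$path[, 2], mean)
    hops_audio <- (as.numeric(names(agg)) - 0.5) * hop
    hops_emg <- (as.numeric(agg) - 0.5) * hop
    t_map <- approx(hops_audio, hops_emg, xout = t_a, rule = 2)$y
    warped <- approx(t_a, up, xout = pmin(pmax(t_map, 0), max(t_a)),
                     rule = 2)$y
    out$warped[[ch]] <- signal_track(warped, audio$rate, units = tr$units,
                                     channel = tr$channel)
    out$paths[[ch]] <- res$path
  }
  out
}

#' Write / read a warp path as two-column integer text
#' @param path warp path matrix.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_warp_path <- function(path, file) {
  write.table(path, file, sep = "\t", row.names = FALSE,
              col.names = c("index_a", "index_b"), quote = FALSE)
  invisible(file)
}

#' @rdname write_warp_path
#' @export
read_warp_path <- function(file)
  as.matrix(read.table(file, header = TRUE, sep = "\t"))
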