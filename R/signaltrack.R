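# Core containers: SignalTrack (one uniformly sampled channel) and Contour
# (a regular time series with undefined gaps), plus their plain-text / WAV IO.

#' Create a SignalTrack
#'
#' A `signal_track` is the carrier for one uniformly sampled channel: the
#' audio waveform or a single sEMG channel.
#'
#' @param samples numeric vector of samples.
#' @param rate sampling rate in Hz (positive scalar).
#' @param units unit label for the samples (informational).
#' @param channel optional channel name.
#' @return an object of class `signal_track`.
#' @export
signal_track <- function(samples, rate, units = "a.u.", channel = NA_character_) {
  stopifnot(is.numeric(samples), is_scalar_num(rate), rate > 0)
  if (anyNA(samples)) stopf("signal_track: samples contain NA")
  structure(
    list(samples = as.numeric(samples), rate = rate, units = units,
         channel = channel),
    class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("<signal_track> %d samples @ %g Hz (%.3f s), units=%s%s\n",
              length(x$samples), x$rate, track_duration(x), x$units,
              if (is.na(x$channel)) "" else paste0(", channel=", x$channel)))
  invisible(x)
}

#' Duration of a SignalTrack in seconds
#' @param track a `signal_track`.
#' @return duration in seconds.
#' @export
track_duration <- function(track) length(track$samples) / track$rate

#' Create a Contour
#'
#' A `contour` is a scalar time series on a strictly uniform grid, with an
#' undefined-mask for frames where the quantity does not exist (e.g. f0
#' during unvoiced spans). Values at undefined points are stored as `NA`.
#'
#' @param times numeric vector of times in seconds, uniform step.
#' @param values numeric values; `NA` marks undefined points.
#' @param unit one of `"Hz"`, `"ST"`, `"dB"`, `"dB SPL"` or another label.
#' @return an object of class `contour`.
#' @export
contour <- function(times, values, unit) {
  stopifnot(length(times) == length(values), is.character(unit))
  if (length(times) > 1L) {
    dt <- diff(times)
    if (any(dt <= 0)) stopf("contour: times must be strictly increasing")
    if (max(dt) - min(dt) > 1e-9 * max(dt, 1))
      stopf("contour: time grid must have a constant step")
  }
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 unit = unit),
            class = "contour")
}

#' @export
print.contour <- function(x, ...) {
  nd <- sum(!is.na(x$values))
  cat(sprintf("<contour> %d points (%d defined), unit=%s, step=%s s\n",
              length(x$times), nd, x$unit,
              if (length(x$times) > 1) format(x$times[2] - x$times[1]) else "NA"))
  invisible(x)
}

#' Evaluate a contour at arbitrary times
#'
#' Linear interpolation between defined points; times that fall inside an
#' undefined gap (nearest grid point undefined) return `NA`.
#'
#' @param cont a `contour`.
#' @param at numeric vector of query times (s).
#' @return numeric vector, `NA` where undefined.
#' @export
contour_at <- function(cont, at) {
  def <- !is.na(cont$values)
  out <- rep(NA_real_, length(at))
  if (sum(def) >= 2L) {
    out <- approx(cont$times[def], cont$values[def], xout = at, rule = 2)$y
  } else if (sum(def) == 1L) {
    out <- rep(cont$values[def], length(at))
  }
  # mask queries whose nearest grid neighbour is undefined
  if (length(cont$times) > 1L) {
    idx <- pmin(pmax(round((at - cont$times[1]) /
                             (cont$times[2] - cont$times[1])) + 1L, 1L),
                length(cont$times))
    out[!def[idx]] <- NA_real_
  } else if (!any(def)) out[] <- NA_real_
  out
}

#' Fraction of contour points that are defined
#' @param cont a `contour`.
#' @return scalar in \[0, 1\].
#' @export
voiced_fraction <- function(cont) mean(!is.na(cont$values))

# ---- plain-text contour IO ------------------------------------------------

#' Write a contour to delimited text
#'
#' Three columns (`time_s`, `value`, `defined`) preceded by a `# unit:` header
#' line. Undefined rows carry value `NA` and flag 0.
#'
#' @param cont a `contour`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_contour <- function(cont, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# unit: %s", cont$unit), con)
  writeLines("time_s\tvalue\tdefined", con)
  writeLines(sprintf("%.9f\t%s\t%d", cont$times,
                     ifelse(is.na(cont$values), "NA",
                            sprintf("%.9g", cont$values)),
                     as.integer(!is.na(cont$values))), con)
  invisible(path)
}

#' Read a contour written by [write_contour()]
#' @param path file path.
#' @return a `contour`.
#' @export
read_contour <- function(path) {
  first <- readLines(path, n = 1L)
  unit <- sub("^# unit: *", "", first)
  d <- read.table(path, header = TRUE, sep = "\t", skip = 1L,
                  na.strings = "NA")
  contour(d$time_s, d$value, unit)
}

# ---- WAV IO ---------------------------------------------------------------
# Minimal RIFF/WAVE support (PCM16 and IEEE float32, mono or multichannel);
# no audio package ships with the environment.

#' Write a SignalTrack to a WAV file
#'
#' @param track a `signal_track` (samples in \[-1, 1\] for PCM).
#' @param path output path.
#' @param bits 16 (integer PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(track, path, bits = 16L) {
  stopifnot(inherits(track, "signal_track"), bits %in% c(16L, 32L))
  x <- track$samples
  n <- length(x)
  fmt <- if (bits == 16L) 1L else 3L
  bytes_per <- bits %/% 8L
  data_len <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_len), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(round(track$rate)), con, size = 4, endian = "little")
  writeBin(as.integer(round(track$rate) * bytes_per), con, size = 4,
           endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_len), con, size = 4, endian = "little")
  if (bits == 16L) {
    q <- as.integer(pmax(pmin(round(x * 32767), 32767), -32768))
    writeBin(q, con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(x), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a WAV file into a SignalTrack
#'
#' Supports mono 16-bit PCM and 32-bit float, as written by [write_wav()].
#'
#' @param path WAV file path.
#' @return a `signal_track`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stopf("not a RIFF file: %s", path)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stopf("not a WAVE file: %s", path)
  fmt <- NULL; rate <- NULL; bits <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) stopf("no data chunk in %s", path)
    len <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), size = 2, endian = "little")
      nch <- readBin(con, integer(), size = 2, endian = "little")
      rate <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      invisible(readBin(con, integer(), size = 2, endian = "little"))
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (nch != 1L) stopf("only mono WAV supported")
      if (len > 16L) invisible(readBin(con, raw(), n = len - 16L))
    } else if (id == "data") {
      n <- len %/% (bits %/% 8L)
      x <- if (fmt == 1L && bits == 16L) {
        readBin(con, integer(), n = n, size = 2, endian = "little",
                signed = TRUE) / 32767
      } else if (fmt == 3L && bits == 32L) {
        readBin(con, numeric(), n = n, size = 4, endian = "little")
      } else stopf("unsupported WAV encoding (fmt %d, %d bit)", fmt, bits)
      return(signal_track(x, rate, units = "normalized amplitude"))
    } else {
      invisible(readBin(con, raw(), n = len + (len %% 2L)))
    }
  }
}
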