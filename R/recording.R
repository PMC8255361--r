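#' Multi-channel recording container
#'
#' Bundles a channels-by-samples voltage matrix with its sampling rate and
#' probe geometry. Traces are kept in the units they were stored in: the
#' pipeline's detection threshold is derived from the data itself, so no
#' amplitude calibration is applied anywhere.
#'
#' @param traces Numeric matrix, channels x samples; row i belongs to the i-th
#'   probe channel.
#' @param sampling_rate Sampling rate in Hz.
#' @param probe An [probe_geometry()].
#' @return An object of class `ht_recording`.
#' @export
recording <- function(traces, sampling_rate, probe) {
  traces <- as.matrix(traces)
  if (!inherits(probe, "ht_probe")) abort("probe must be an ht_probe")
  if (nrow(traces) != nrow(probe)) {
    abort(sprintf(
      "traces has %d rows but the probe declares %d channels",
      nrow(traces), nrow(probe)
    ))
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 || sampling_rate <= 0) {
    abort("sampling_rate must be a single positive number (Hz)")
  }
  if (!all(is.finite(traces))) abort("all trace samples must be finite")
  structure(
    list(traces = traces, sampling_rate = as.numeric(sampling_rate), probe = probe),
    class = "ht_recording"
  )
}

#' @export
print.ht_recording <- function(x, ...) {
  cat(sprintf(
    "<ht_recording> %d channels x %d samples @ %g Hz (%.2f s)\n",
    nrow(x$traces), ncol(x$traces), x$sampling_rate,
    ncol(x$traces) / x$sampling_rate
  ))
  invisible(x)
}

#' @export
dim.ht_recording <- function(x) dim(x$traces)

#' Read a flat binary recording
#'
#' Reads raw traces from a headerless binary file of int16 or float32 samples,
#' either channel-interleaved (sample-major: c1s1, c2s1, ...) or channel-major
#' (c1s1, c1s2, ...). No scaling is applied.
#'
#' @param path Path to the binary file.
#' @param probe An [probe_geometry()] or a path to a probe JSON file.
#' @param sampling_rate Sampling rate in Hz.
#' @param layout `"interleaved"` or `"channel-major"`.
#' @param dtype `"int16"` or `"float32"`.
#' @return An `ht_recording`.
#' @export
read_recording <- function(path, probe, sampling_rate,
                           layout = c("interleaved", "channel-major"),
                           dtype = c("int16", "float32")) {
  layout <- match.arg(layout)
  dtype <- match.arg(dtype)
  if (is.character(probe)) probe <- read_probe(probe)
  n_ch <- nrow(probe)
  width <- switch(dtype, int16 = 2L, float32 = 4L)
  n_bytes <- file.size(path)
  if (is.na(n_bytes)) abort(sprintf("cannot read '%s'", path))
  if (n_bytes %% (n_ch * width) != 0) {
    abort(sprintf(
      "file size %d bytes is not a whole number of %d-channel %s frames (expected a multiple of %d bytes)",
      n_bytes, n_ch, dtype, n_ch * width
    ))
  }
  n_total <- n_bytes / width
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- switch(dtype,
    int16 = readBin(con, "integer", n = n_total, size = 2L, signed = TRUE, endian = "little"),
    float32 = readBin(con, "double", n = n_total, size = 4L, endian = "little")
  )
  traces <- if (layout == "interleaved") {
    matrix(as.numeric(vals), nrow = n_ch) # frame-by-frame columns
  } else {
    t(matrix(as.numeric(vals), ncol = n_ch))
  }
  recording(traces, sampling_rate, probe)
}

#' @rdname read_recording
#' @param rec An `ht_recording`.
#' @return `write_recording()` returns `path` invisibly.
#' @export
write_recording <- function(rec, path, layout = c("interleaved", "channel-major"),
                            dtype = c("int16", "float32")) {
  layout <- match.arg(layout)
  dtype <- match.arg(dtype)
  vals <- if (layout == "interleaved") as.vector(rec$traces) else as.vector(t(rec$traces))
  con <- file(path, "wb")
  on.exit(close(con))
  if (dtype == "int16") {
    v <- as.integer(round(vals))
    if (any(abs(v) > 32767)) abort("traces exceed int16 range; write as float32")
    writeBin(v, con, size = 2L, endian = "little")
  } else {
    writeBin(as.numeric(vals), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Zero-phase bandpass filter
#'
#' Applies a 3rd-order Butterworth bandpass forward and backward
#' ([signal::filtfilt()]), giving zero phase distortion so that the later peak
#' alignment is not biased by filter delay. The conventional band for
#' extracellular spikes is 300--3000 Hz.
#'
#' @param rec An `ht_recording`.
#' @param low,high Band edges in Hz; requires `0 < low < high < rate/2`.
#' @param order Butterworth order (per pass).
#' @return A filtered `ht_recording` of identical shape.
#' @export
bandpass <- function(rec, low = 300, high = 3000, order = 3) {
  nyq <- rec$sampling_rate / 2
  if (!(low > 0 && low < high && high < nyq)) {
    abort(sprintf("band edges must satisfy 0 < low < high < Nyquist (%g Hz)", nyq))
  }
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  out <- t(apply(rec$traces, 1, function(x) signal::filtfilt(bf, x)))
  recording(out, rec$sampling_rate, rec$probe)
}

#' Resample a recording
#'
#' Polyphase rational-ratio resampling with anti-aliasing
#' ([signal::resample()]). A typical use is downsampling 30 kHz acquisition to
#' the 14 kHz working rate, which keeps enough bandwidth for the 300--3000 Hz
#' spike band while roughly halving the data volume.
#'
#' @param rec An `ht_recording`.
#' @param target_rate Target sampling rate in Hz.
#' @return An `ht_recording` at `target_rate`; unchanged if already there.
#' @export
resample_recording <- function(rec, target_rate = 14000) {
  if (!is.numeric(target_rate) || target_rate <= 0) abort("target_rate must be positive")
  if (target_rate == rec$sampling_rate) return(rec)
  fr <- ratio_pq(target_rate / rec$sampling_rate)
  out <- t(apply(rec$traces, 1, function(x) as.numeric(signal::resample(x, fr[1], fr[2]))))
  recording(out, target_rate, rec$probe)
}

# small rational approximation p/q of a rate ratio
ratio_pq <- function(r, max_den = 10000L) {
  # continued-fraction expansion
  p0 <- 0L; q0 <- 1L; p1 <- 1L; q1 <- 0L
  x <- r
  repeat {
    a <- floor(x)
    p2 <- as.integer(a * p1 + p0); q2 <- as.integer(a * q1 + q0)
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - r) < 1e-12) break
    x <- 1 / (x - a)
  }
  c(p1, q1)
}
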