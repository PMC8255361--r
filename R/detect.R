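#' Detection parameters
#'
#' @param k Threshold multiplier on the robust noise estimate; conventionally
#'   between 3 and 5 (warned outside that range, any positive value accepted).
#' @param wnd_ms Snippet window length in milliseconds.
#' @param p Peak alignment position as a fraction of the window (0.5 centers
#'   the peak).
#' @return A list of class `ht_detection_params`.
#' @export
detection_params <- function(k = 4, wnd_ms = 3, p = 0.5) {
  stopifnot(is.numeric(k), length(k) == 1, k > 0)
  if (k < 3 || k > 5) warn(sprintf("k = %g is outside the usual 3-5 range", k))
  stopifnot(wnd_ms > 0, p > 0, p < 1)
  structure(list(k = k, wnd_ms = wnd_ms, p = p), class = "ht_detection_params")
}

#' Robust noise standard deviation (median absolute deviation)
#'
#' Estimates the background-noise standard deviation of a trace as
#' `median(|x|) / 0.6745`. The denominator is the inverse standard-normal CDF
#' at 0.75, so that the estimator is unbiased for pure Gaussian noise; using
#' the median of absolute values makes it nearly insensitive to the sparse
#' large-amplitude spikes that inflate the plain standard deviation.
#'
#' @param trace Numeric vector, one channel's voltage samples.
#' @return The estimated noise sigma (same units as the trace).
#' @examples
#' estimate_noise_sigma(c(-1, 0, 1)) # 1 / 0.6745
#' @export
estimate_noise_sigma <- function(trace) {
  if (length(trace) == 0) abort("trace must be nonempty")
  if (!all(is.finite(trace))) abort("trace must be finite")
  median(abs(trace)) / MAD_DENOMINATOR
}

#' Detection threshold
#'
#' @param sigma Noise standard deviation estimate (voltage).
#' @param k Dimensionless multiplier.
#' @return `k * sigma`.
#' @export
compute_threshold <- function(sigma, k = 4) {
  stopifnot(sigma >= 0, k > 0)
  k * sigma
}

# window start offset before the peak for length L and alignment fraction p
align_offset <- function(L, p) floor(p * L)

snippet_length <- function(wnd_ms, sampling_rate) {
  as.integer(round(wnd_ms * sampling_rate / 1000))
}

#' Detect peak-aligned snippets on one channel
#'
#' Slides a window of `wnd_ms` over the trace and emits a snippet at every
#' index whose absolute amplitude exceeds the threshold and is the strict
#' maximum of absolute values within its window (on exact ties, only the
#' earliest index is kept). Both polarities are detected. Windows overhanging
#' either end of the trace are discarded.
#'
#' @param trace Numeric vector of one channel's (filtered) samples.
#' @param sampling_rate Hz.
#' @param params A [detection_params()].
#' @param channel Channel id recorded in the output.
#' @param threshold Optional explicit absolute threshold (voltage); by default
#'   computed from the trace as `k * estimate_noise_sigma(trace)`.
#' @return A tibble with one row per snippet: `channel`, `peak_index` (1-based
#'   sample index of the aligned peak), `peak_amplitude` (absolute voltage),
#'   and `waveform` (list column of length-L numeric vectors). Attributes
#'   `snippet_length`, `align_offset` and `threshold` describe the run.
#' @export
detect_snippets <- function(trace, sampling_rate, params = detection_params(),
                            channel = 0L, threshold = NULL) {
  L <- snippet_length(params$wnd_ms, sampling_rate)
  if (length(trace) <= L) abort("trace must be longer than one window")
  off <- align_offset(L, params$p)
  thr <- threshold %||% compute_threshold(estimate_noise_sigma(trace), params$k)

  a <- abs(trace)
  cand <- which(a > thr)
  # windows overhanging the boundary are dropped (cannot be aligned)
  cand <- cand[cand - off >= 1 & cand - off + L - 1 <= length(trace)]
  keep <- vapply(cand, function(i) {
    w <- a[(i - off):(i - off + L - 1)]
    m <- max(w)
    a[i] == m && which.max(w) == off + 1 # strict max; earliest index on ties
  }, logical(1))
  cand <- cand[keep]

  out <- tibble::tibble(
    channel = as.integer(channel),
    peak_index = as.integer(cand),
    peak_amplitude = a[cand],
    waveform = lapply(cand, function(i) trace[(i - off):(i - off + L - 1)])
  )
  attr(out, "snippet_length") <- L
  attr(out, "align_offset") <- off
  attr(out, "threshold") <- thr
  out
}

#' Sub-sample peak re-alignment of snippets
#'
#' At working rates of ~14 kHz a sharp spike trough spans only a few samples,
#' so the integer peak index is off by up to half a sample from the true
#' extremum. That jitter broadens feature-space clusters and can split one
#' unit into alignment classes. This step estimates the fractional peak
#' offset by a three-point parabolic fit around the peak and resamples each
#' waveform (cubic spline) so the true extremum lands exactly on the
#' alignment position. Peak indices and amplitudes are left untouched.
#'
#' @param snippets A snippet tibble from [detect_snippets()] or
#'   [detect_all()].
#' @return The tibble with interpolated `waveform`s.
#' @export
align_snippets <- function(snippets) {
  off <- attr(snippets, "align_offset")
  if (nrow(snippets) == 0) return(snippets)
  snippets$waveform <- lapply(snippets$waveform, function(w) {
    p <- off + 1L
    y1 <- abs(w[p - 1]); y2 <- abs(w[p]); y3 <- abs(w[p + 1])
    den <- y1 - 2 * y2 + y3
    delta <- if (abs(den) < .Machine$double.eps) 0 else 0.5 * (y1 - y3) / den
    delta <- max(min(delta, 0.5), -0.5)
    if (delta == 0) return(w)
    n <- length(w)
    stats::spline(seq_len(n), w, xout = pmin(pmax(seq_len(n) + delta, 1), n))$y
  })
  snippets
}

#' Detect snippets on every channel of a recording
#'
#' Runs [detect_snippets()] independently per channel, each channel with its
#' own data-derived threshold. The result is identical whether channels are
#' processed serially or in parallel; this implementation is serial and
#' deterministic.
#'
#' @param rec An `ht_recording` (already bandpass filtered).
#' @param params A [detection_params()].
#' @param thresholds Optional named numeric vector of per-channel absolute
#'   thresholds overriding the data-derived ones.
#' @return A tibble of snippets over all channels, ordered by channel then
#'   `peak_index`, with attributes `snippet_length`, `align_offset`,
#'   `thresholds` (named per-channel vector) and `sampling_rate`.
#' @export
detect_all <- function(rec, params = detection_params(), thresholds = NULL) {
  chans <- rec$probe$channel_id
  per <- lapply(seq_along(chans), function(i) {
    thr <- if (!is.null(thresholds)) unname(thresholds[as.character(chans[i])]) else NULL
    detect_snippets(rec$traces[i, ], rec$sampling_rate, params,
      channel = chans[i], threshold = thr
    )
  })
  thr_vec <- vapply(per, attr, numeric(1), which = "threshold")
  names(thr_vec) <- chans
  out <- dplyr::bind_rows(per)
  attr(out, "snippet_length") <- attr(per[[1]], "snippet_length")
  attr(out, "align_offset") <- attr(per[[1]], "align_offset")
  attr(out, "thresholds") <- thr_vec
  attr(out, "sampling_rate") <- rec$sampling_rate
  out
}
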