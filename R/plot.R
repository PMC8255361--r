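#' Plot a recording's traces
#'
#' Channel-stacked voltage traces for a time window; a quick visual check of
#' noise level and spike footprint spread.
#'
#' @param object An `ht_recording`.
#' @param t_start,t_end Window in seconds (defaults to the first 0.5 s).
#' @param spacing Vertical offset between channels, in units of the median
#'   per-channel robust noise sigma.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ht_recording <- function(object, t_start = 0, t_end = NULL, spacing = 10, ...) {
  fs <- object$sampling_rate
  t_end <- t_end %||% min(0.5, ncol(object$traces) / fs)
  i0 <- max(1L, floor(t_start * fs) + 1L)
  i1 <- min(ncol(object$traces), ceiling(t_end * fs))
  sig <- median(apply(object$traces[, i0:i1, drop = FALSE], 1, estimate_noise_sigma))
  step <- spacing * max(sig, .Machine$double.eps)
  df <- purrr::map_dfr(seq_len(nrow(object$traces)), function(ch) {
    tibble::tibble(
      time_s = (i0:i1 - 1) / fs,
      voltage = object$traces[ch, i0:i1] + (ch - 1) * step,
      channel = factor(object$probe$channel_id[ch])
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$voltage, group = .data$channel)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "time (s)", y = "voltage (offset per channel)") +
    ggplot2::theme_minimal()
}

#' Plot a template library
#'
#' @param object An `ht_templates`.
#' @param ... Unused.
#' @return A ggplot object with one facet per template.
#' @export
autoplot.ht_templates <- function(object, ...) {
  fs <- attr(object, "sampling_rate") %||% 1000
  df <- purrr::map_dfr(seq_len(nrow(object)), function(i) {
    w <- object$waveform[[i]]
    tibble::tibble(
      t_ms = (seq_along(w) - 1) / fs * 1000,
      voltage = w,
      template = factor(object$template_id[i])
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$t_ms, .data$voltage)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~template, scales = "free_y") +
    ggplot2::labs(x = "time (ms)", y = "voltage") +
    ggplot2::theme_minimal()
}

#' Plot the per-group feature spaces of a sorting result
#'
#' 2-D principal-component scatter of every electrode group, colored by
#' cluster label; outliers (label -1) in black.
#'
#' @param object An `ht_sort`.
#' @param ... Unused.
#' @return A ggplot object faceted by group channel.
#' @export
autoplot.ht_sort <- function(object, ...) {
  df <- object$labeled[!is.na(object$labeled$pc1), , drop = FALSE]
  clustered <- df[df$label >= 0, , drop = FALSE]
  outliers <- df[df$label < 0, , drop = FALSE]
  clustered$label <- factor(clustered$label)
  ggplot2::ggplot(clustered, ggplot2::aes(.data$pc1, .data$pc2)) +
    ggplot2::geom_point(ggplot2::aes(color = .data$label), size = 0.7, alpha = 0.8) +
    ggplot2::geom_point(data = outliers, color = "black", size = 0.7, shape = 4) +
    ggplot2::guides(color = "none") +
    ggplot2::facet_wrap(~channel, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "PC1", y = "PC2") +
    ggplot2::theme_minimal()
}
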