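#' Coalesce multi-channel detections into spike events
#'
#' A spike close to several contacts is detected on each of them. Two snippets
#' are taken to witness the same physical spike iff their peaks lie within
#' `delta_t_ms` of each other and their channels are probe neighbors; the
#' relation is closed transitively, so an event may chain across a run of
#' adjacent channels. Every snippet belongs to exactly one event.
#'
#' @param snippets A snippet tibble from [detect_all()].
#' @param probe An [probe_geometry()].
#' @param delta_t_ms Coincidence window in milliseconds. Should be smaller
#'   than half the snippet window; a warning is raised otherwise.
#' @param sampling_rate Hz; defaults to the snippet table's attribute.
#' @return The snippet tibble with an `event_id` column (1..n_events, in order
#'   of each event's earliest peak).
#' @export
coalesce_events <- function(snippets, probe, delta_t_ms = 0.5,
                            sampling_rate = attr(snippets, "sampling_rate")) {
  if (is.null(sampling_rate)) abort("sampling_rate is required")
  L <- attr(snippets, "snippet_length")
  if (!is.null(L) && delta_t_ms * sampling_rate / 1000 >= L / 2) {
    warn("coincidence window delta_t is not smaller than half the snippet window")
  }
  n <- nrow(snippets)
  if (n == 0) {
    return(dplyr::mutate(snippets, event_id = integer(0)))
  }
  delta <- delta_t_ms * sampling_rate / 1000
  nb <- probe_neighbors(probe)
  ord <- order(snippets$peak_index, snippets$channel)
  pk <- snippets$peak_index[ord]
  ch <- as.character(snippets$channel[ord])

  parent <- uf_new(n)
  j0 <- 1L
  for (i in seq_len(n)) {
    while (pk[i] - pk[j0] > delta) j0 <- j0 + 1L
    if (j0 < i) {
      for (j in j0:(i - 1L)) {
        if (nb[ch[i], ch[j]]) parent <- uf_union(parent, j, i)
      }
    }
  }
  comp <- uf_components(parent)
  event_id <- integer(n)
  event_id[ord] <- comp
  out <- dplyr::mutate(snippets, event_id = event_id)
  attr(out, "snippet_length") <- attr(snippets, "snippet_length")
  attr(out, "align_offset") <- attr(snippets, "align_offset")
  attr(out, "thresholds") <- attr(snippets, "thresholds")
  attr(out, "sampling_rate") <- sampling_rate
  out
}

#' Keep only the best-channel snippet of each event
#'
#' Within each coalesced event, only the member with the largest absolute peak
#' amplitude is retained as the estimate of the spike waveform; ties break to
#' the lowest channel id. This suppresses cross-channel duplicates while the
#' retained channel carries the spatial identity of the event.
#'
#' @param events Snippet tibble with `event_id` from [coalesce_events()].
#' @return A tibble with one row per event (columns as the input plus
#'   `n_members`), ordered by `peak_index`.
#' @export
select_best_channels <- function(events) {
  out <- events |>
    dplyr::group_by(.data$event_id) |>
    dplyr::arrange(dplyr::desc(.data$peak_amplitude), .data$channel, .by_group = TRUE) |>
    dplyr::mutate(n_members = dplyr::n()) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$peak_index)
  for (a in c("snippet_length", "align_offset", "thresholds", "sampling_rate")) {
    attr(out, a) <- attr(events, a)
  }
  out
}

#' Split retained snippets into per-electrode groups
#'
#' Groups the best-channel snippets by their channel of origin: all spikes
#' whose strongest footprint is on electrode `chA` form group `gpA`. Grouping
#' by electrode is a spatial pre-clustering — units at different locations
#' with near-identical waveforms end up in different groups.
#'
#' @param retained Output of [select_best_channels()].
#' @return A named list of snippet tibbles, one per channel that owns at least
#'   one snippet; names are the channel ids.
#' @export
build_groups <- function(retained) {
  if (nrow(retained) == 0) return(structure(list(), names = character(0)))
  split_ids <- factor(retained$channel, levels = sort(unique(retained$channel)))
  groups <- split(retained, split_ids)
  for (g in names(groups)) {
    for (a in c("snippet_length", "align_offset", "sampling_rate")) {
      attr(groups[[g]], a) <- attr(retained, a)
    }
  }
  groups
}
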