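#' Pipeline configuration
#'
#' Collects every stage parameter with its default. Unknown names are
#' rejected so a typo cannot silently fall back to a default.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return A list of class `ht_config`.
#' @details Defaults: bandpass 300--3000 Hz (3rd-order zero-phase
#'   Butterworth), working rate 14000 Hz, detection `k = 4`, window 3 ms,
#'   alignment fraction 0.5, coincidence window 0.5 ms, PCA components 2,
#'   `min_cluster_size = 10`, `min_samples = 5`, merge sigma 0.15, shared
#'   space dimension 5, neighbor radius from the probe, pursuit acceptance
#'   0.8 with cap 5, evaluation tolerance 1 ms.
#' @export
htsort_config <- function(...) {
  defaults <- list(
    bandpass_low = 300, bandpass_high = 3000, filter_order = 3,
    target_rate = 14000,
    k = 4, wnd_ms = 3, p = 0.5, align_interpolate = TRUE,
    delta_t_ms = 0.5,
    n_components = 2, min_cluster_size = 10, min_samples = 5,
    merge_sigma = 0.15, n_shared_components = 5, merge_weighted = TRUE,
    min_template_snr = 6,
    accept_threshold = 0.8, max_pursuit = 5, scale_subtraction = TRUE,
    metric = "ncc",
    tol_ms = 1.0
  )
  over <- list(...)
  if (length(over) == 1 && is.list(over[[1]]) && is.null(names(over))) over <- over[[1]]
  bad <- setdiff(names(over), names(defaults))
  if (length(bad) > 0) {
    abort(sprintf("unknown configuration keys: %s", paste(bad, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, over)
  structure(cfg, class = "ht_config")
}

#' Read / write a pipeline configuration as JSON
#' @param path File path.
#' @return An `ht_config` / `path` invisibly.
#' @export
read_config <- function(path) {
  htsort_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname read_config
#' @param config An `ht_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the full spike-sorting pipeline
#'
#' Executes, in order: bandpass filtering, resampling to the working rate,
#' per-channel threshold detection with peak alignment, divide-and-conquer
#' event coalescing and best-channel selection, per-group PCA + density
#' clustering with outlier marking, template estimation and cross-electrode
#' merging, and greedy template-matching pursuit of the outliers. All stages
#' are deterministic: the same recording and configuration always give
#' identical output.
#'
#' @param rec An `ht_recording` (raw; filtering/resampling happen inside,
#'   set `preprocess = FALSE` if `rec` is already filtered at the working
#'   rate).
#' @param config An [htsort_config()].
#' @param preprocess Apply bandpass/resampling.
#' @return An object of class `ht_sort`: list with `spikes` (tibble:
#'   `peak_index`, `time_s`, `unit`, `channel`, `source`, `score`),
#'   `templates` (merged `ht_templates`), `labeled` (per-snippet clustering
#'   table), `report` (per-stage counts), `config`, `sampling_rate`.
#' @examples
#' sim <- render_recording(simulation_spec(n_channels = 4, n_units = 2,
#'   duration_s = 4, seed = 7))
#' res <- run_pipeline(sim$recording)
#' tidy(res)
#' @export
run_pipeline <- function(rec, config = htsort_config(), preprocess = TRUE) {
  stopifnot(inherits(rec, "ht_recording"))
  if (preprocess) {
    rec <- bandpass(rec, config$bandpass_low, config$bandpass_high, config$filter_order)
    rec <- resample_recording(rec, config$target_rate)
  }
  params <- detection_params(config$k, config$wnd_ms, config$p)

  snippets <- detect_all(rec, params)
  thresholds <- attr(snippets, "thresholds")
  if (isTRUE(config$align_interpolate)) snippets <- align_snippets(snippets)

  events <- coalesce_events(snippets, rec$probe, config$delta_t_ms)
  retained <- select_best_channels(events)
  groups <- build_groups(retained)

  labeled <- cluster_all(groups, config$n_components, config$min_cluster_size,
    config$min_samples
  )

  library0 <- estimate_templates(labeled)
  noise_sigmas <- thresholds / config$k
  scr <- screen_templates(library0, labeled, noise_sigmas, config$min_template_snr)
  n_screened <- nrow(library0) - nrow(scr$library)
  library0 <- scr$library
  labeled <- scr$labeled
  library0 <- build_shared_space(library0, config$n_shared_components)
  library <- merge_templates(library0, rec$probe,
    merge_sigma = config$merge_sigma,
    weighted = config$merge_weighted,
    n_components = config$n_shared_components,
    noise_sigmas = noise_sigmas
  )
  provenance <- attr(library, "provenance")

  clustered <- labeled[!is.na(labeled$cluster_key), , drop = FALSE]
  cluster_spikes <- tibble::tibble(
    peak_index = clustered$peak_index,
    unit = unname(provenance[clustered$cluster_key]),
    channel = clustered$channel,
    source = "cluster",
    score = NA_real_
  )

  pursued <- resolve_outliers(labeled, library, rec, thresholds,
    noise_sigmas = noise_sigmas, min_snr = config$min_template_snr,
    accept_threshold = config$accept_threshold,
    max_iter = config$max_pursuit,
    scale_subtraction = config$scale_subtraction,
    metric = config$metric
  )
  pursuit_spikes <- tibble::tibble(
    peak_index = pursued$peak_index,
    unit = pursued$unit,
    channel = pursued$channel,
    source = "pursuit",
    score = pursued$score
  )

  spikes <- dplyr::bind_rows(cluster_spikes, pursuit_spikes) |>
    dplyr::mutate(time_s = (.data$peak_index - 1) / rec$sampling_rate) |>
    dplyr::arrange(.data$peak_index) |>
    dplyr::select("peak_index", "time_s", "unit", "channel", "source", "score")

  n_outliers <- sum(labeled$label == -1L)
  report <- list(
    n_channels = nrow(rec$probe),
    n_samples = ncol(rec$traces),
    sampling_rate = rec$sampling_rate,
    snippets_detected = nrow(snippets),
    events_coalesced = max(events$event_id, 0L),
    duplicates_suppressed = nrow(snippets) - nrow(retained),
    clustered_spikes = nrow(clustered),
    outliers = n_outliers,
    templates_screened_out = n_screened,
    templates_premerge = nrow(library0),
    templates_postmerge = nrow(library),
    pursuit_accepted = nrow(pursuit_spikes),
    outliers_discarded = n_outliers, # segments, of which some yielded spikes
    sorted_spikes = nrow(spikes)
  )
  structure(
    list(
      spikes = spikes, templates = library, labeled = labeled,
      thresholds = thresholds, report = report, config = config,
      sampling_rate = rec$sampling_rate
    ),
    class = "ht_sort"
  )
}

#' @export
print.ht_sort <- function(x, ...) {
  r <- x$report
  cat("<ht_sort>\n")
  cat(sprintf(
    "  %d channels x %d samples @ %g Hz\n",
    r$n_channels, r$n_samples, r$sampling_rate
  ))
  cat(sprintf(
    "  snippets %d -> events %d -> clustered %d + outliers %d\n",
    r$snippets_detected, r$events_coalesced, r$clustered_spikes, r$outliers
  ))
  cat(sprintf(
    "  templates %d -> %d after merging; pursuit recovered %d\n",
    r$templates_premerge, r$templates_postmerge, r$pursuit_accepted
  ))
  cat(sprintf("  %d sorted spikes in %d units\n", r$sorted_spikes,
    length(unique(x$spikes$unit))))
  invisible(x)
}

#' @export
tidy.ht_sort <- function(x, ...) x$spikes

#' @export
glance.ht_sort <- function(x, ...) tibble::as_tibble(x$report)

#' Evaluate a pipeline result against simulation ground truth
#'
#' @param result An `ht_sort`.
#' @param truth The `truth` element of an [render_recording()] simulation.
#' @param tol_ms Pairing tolerance (defaults to the result's configuration).
#' @return An `ht_evaluation` (see [match_spikes()]).
#' @export
evaluate_sorting <- function(result, truth, tol_ms = NULL) {
  tol_ms <- tol_ms %||% result$config$tol_ms
  match_spikes(truth$spikes, result$spikes, result$sampling_rate, tol_ms)
}
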