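#' Estimate per-cluster templates
#'
#' The template of a cluster is the pointwise mean of its member waveforms
#' (mean, not median, so that later cross-template averaging during merging
#' stays consistent with the estimation stage).
#'
#' @param labeled Snippet tibble from [cluster_all()] (needs `cluster_key`,
#'   `channel`, `waveform`).
#' @return A template library tibble of class `ht_templates`: one row per
#'   cluster with `template_id`, `home_channels` (list), `n_spikes`,
#'   `waveform` (list of mean waveforms) and `source_keys` (list of the
#'   cluster keys merged into the row — one key each before merging).
#' @export
estimate_templates <- function(labeled) {
  members <- labeled[!is.na(labeled$cluster_key), , drop = FALSE]
  if (nrow(members) == 0) {
    return(empty_template_library(labeled))
  }
  lib <- members |>
    dplyr::group_by(.data$cluster_key) |>
    dplyr::summarise(
      home_channels = list(unique(.data$channel)),
      n_spikes = dplyr::n(),
      waveform = list(colMeans(do.call(rbind, .data$waveform))),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$cluster_key)
  lib <- dplyr::mutate(lib,
    template_id = dplyr::row_number() - 1L,
    source_keys = lapply(.data$cluster_key, identity)
  )
  lib <- dplyr::select(
    lib, "template_id", "home_channels", "n_spikes", "waveform", "source_keys"
  )
  class(lib) <- c("ht_templates", class(lib))
  attr(lib, "snippet_length") <- attr(labeled, "snippet_length")
  attr(lib, "align_offset") <- attr(labeled, "align_offset")
  attr(lib, "sampling_rate") <- attr(labeled, "sampling_rate")
  lib
}

empty_template_library <- function(labeled) {
  lib <- tibble::tibble(
    template_id = integer(0), home_channels = list(), n_spikes = integer(0),
    waveform = list(), source_keys = list()
  )
  class(lib) <- c("ht_templates", class(lib))
  attr(lib, "snippet_length") <- attr(labeled, "snippet_length")
  attr(lib, "align_offset") <- attr(labeled, "align_offset")
  attr(lib, "sampling_rate") <- attr(labeled, "sampling_rate")
  lib
}

#' Screen out sub-threshold templates
#'
#' With a lenient detection threshold, chance noise crossings can be frequent
#' enough to form their own small dense cluster in a group's feature space.
#' Averaging such a cluster yields a "template" whose peak barely exceeds the
#' detection level, whereas a genuine unit's template clears it severalfold.
#' This screen keeps a cluster only if its template peak reaches
#' `min_snr` times the home channel's noise sigma. The default of 6 sits
#' between the two populations the screen must separate: averaged chance
#' crossings peak near 4.3 sigma (upper tail ~5), while any unit satisfying
#' the pipeline's working assumption of raw SNR >= 8 keeps a filtered
#' template peak of at least ~7.5 sigma even for the sharpest troughs the
#' 300--3000 Hz band permits. Members of rejected clusters are returned to
#' the outlier pool, where pursuit discards them unless they match a real
#' template.
#'
#' @param library An `ht_templates` tibble (pre-merge).
#' @param labeled The [cluster_all()] snippet table the library came from.
#' @param noise_sigmas Named per-channel noise sigma estimates.
#' @param min_snr Required template peak in units of the channel noise sigma.
#' @return A list with the screened `library` and the updated `labeled`
#'   (members of dropped clusters relabeled as outliers).
#' @export
screen_templates <- function(library, labeled, noise_sigmas, min_snr = 6) {
  if (nrow(library) == 0) {
    return(list(library = library, labeled = labeled))
  }
  peak <- vapply(library$waveform, function(w) max(abs(w)), numeric(1))
  home_sigma <- vapply(library$home_channels, function(ch) {
    max(unname(noise_sigmas[as.character(ch)]))
  }, numeric(1))
  keep <- peak >= min_snr * home_sigma
  dropped_keys <- unlist(library$source_keys[!keep])
  out_lib <- library[keep, , drop = FALSE]
  out_lib$template_id <- seq_len(nrow(out_lib)) - 1L
  for (a in c("snippet_length", "align_offset", "sampling_rate")) {
    attr(out_lib, a) <- attr(library, a)
  }
  if (length(dropped_keys) > 0) {
    hit <- labeled$cluster_key %in% dropped_keys
    labeled$label[hit] <- -1L
    labeled$cluster_key[hit] <- NA_character_
  }
  list(library = out_lib, labeled = labeled)
}

#' Shared comparison space for templates
#'
#' Each group's PCA space is fit on its own snippets, so coordinates from
#' different groups are not comparable. For merging, every template waveform
#' is therefore peak-normalized (divided by its peak absolute amplitude,
#' making the comparison scale-free, which is what a dimensionless distance
#' threshold like 0.05 implies) and projected onto a PCA basis fit on the
#' normalized template waveforms themselves. Euclidean distance in this space
#' is the merge metric.
#'
#' @param library An `ht_templates` tibble.
#' @param n_components Dimension of the shared space (capped by the number of
#'   templates and the waveform length).
#' @return The library with a `feature_vector` list column added.
#' @export
build_shared_space <- function(library, n_components = 5) {
  if (nrow(library) == 0) {
    library$feature_vector <- list()
    return(library)
  }
  w <- do.call(rbind, library$waveform)
  peak <- apply(abs(w), 1, max)
  peak[peak == 0] <- 1
  wn <- w / peak
  k <- max(1L, min(n_components, nrow(wn) - 1L, ncol(wn)))
  if (nrow(wn) == 1) {
    library$feature_vector <- list(rep(0, k))
    attr(library, "shared_basis") <- list(
      rotation = diag(ncol(wn))[, seq_len(k), drop = FALSE],
      center = rep(0, ncol(wn))
    )
    return(library)
  }
  pc <- prcomp(wn, center = TRUE, scale. = FALSE)
  k <- min(k, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  library$feature_vector <- lapply(seq_len(nrow(scores)), function(i) scores[i, ])
  attr(library, "shared_basis") <- list(
    rotation = pc$rotation[, seq_len(k), drop = FALSE],
    center = pc$center
  )
  library
}

# waveform shifted by `lag` samples (fractional allowed, cubic spline
# interpolation, edge values held)
shift_waveform <- function(w, lag) {
  if (lag == 0) return(w)
  n <- length(w)
  xo <- pmin(pmax(seq_len(n) - lag, 1), n)
  stats::spline(seq_len(n), w, xout = xo)$y
}

# merge distance between templates i and j: Euclidean distance of their
# peak-normalized waveforms in the shared space, minimized over sub-sample
# relative lags — discrete peak alignment jitters a sharp trough by up to
# half a sample, which must not masquerade as a shape difference
merge_distance <- function(wn_i, wn_j, basis, max_lag = 2, lag_step = 0.25) {
  proj <- function(w) drop(crossprod(basis$rotation, w - basis$center))
  pi_ <- proj(wn_i)
  lags <- seq(-max_lag, max_lag, by = lag_step)
  min(vapply(lags, function(s) {
    sqrt(sum((pi_ - proj(shift_waveform(wn_j, s)))^2))
  }, numeric(1)))
}

#' Merge redundant templates across neighboring electrodes
#'
#' A unit lying between two contacts is detected sometimes on one, sometimes
#' on the other, producing near-identical templates in both groups; discrete
#' peak alignment can likewise split one unit into jitter-shifted clusters
#' within a single group. Two templates are merged iff (1) their distance in
#' the shared comparison space, minimized over relative lags of up to
#' `max_lag` samples, is below `merge_sigma` and (2) they live on the same
#' electrode or on neighboring electrodes.
#' The pairwise relation is closed transitively (union-find), making the
#' result independent of template order and idempotent. Each merged group is
#' replaced by the coordinate-wise mean of its member templates, by default
#' weighted by member-spike counts so a small spur cannot drag a
#' well-supported template (the unweighted mean is available with
#' `weighted = FALSE`).
#'
#' @param library An `ht_templates` tibble (feature vectors are built with
#'   [build_shared_space()] if absent).
#' @param probe An [probe_geometry()].
#' @param merge_sigma Dimensionless distance threshold in the shared space.
#' @param weighted Weight the merged mean by `n_spikes`.
#' @param n_components Shared-space dimension (see [build_shared_space()]).
#' @param max_lag Largest relative alignment shift (samples) tried when
#'   comparing two templates.
#' @param noise_sigmas Optional named per-channel noise sigma estimates. When
#'   given, the merge threshold for a pair widens from `merge_sigma` to
#'   `sqrt(merge_sigma^2 + z^2 * k * (s_i^2 + s_j^2))` where
#'   `s_t = sigma_hat / (sqrt(n_spikes) * peak)` is template `t`'s expected
#'   per-sample estimation noise after peak normalization, `k` the shared
#'   space dimension and `z = 2`: a pair of templates whose distance is
#'   statistically indistinguishable from pure estimation noise is merged
#'   even if a few dim spikes made the fixed threshold unreachable.
#' @return A merged `ht_templates` tibble with a `provenance` attribute
#'   mapping every original cluster key to its merged `template_id`.
#' @export
merge_templates <- function(library, probe, merge_sigma = 0.15, weighted = TRUE,
                            n_components = 5, max_lag = 2, noise_sigmas = NULL) {
  if (nrow(library) == 0) {
    attr(library, "provenance") <- structure(integer(0), names = character(0))
    return(library)
  }
  if (is.null(library$feature_vector) || is.null(attr(library, "shared_basis"))) {
    library <- build_shared_space(library, n_components)
  }
  n <- nrow(library)
  basis <- attr(library, "shared_basis")
  w <- do.call(rbind, library$waveform)
  peak <- apply(abs(w), 1, max)
  peak[peak == 0] <- 1
  wn <- w / peak
  pd <- probe_distances(probe)
  thres_nb <- attr(probe, "thres_nb")
  k_dim <- ncol(basis$rotation)

  # expected per-sample estimation noise of each normalized template
  s_t <- if (is.null(noise_sigmas)) rep(0, n) else vapply(seq_len(n), function(i) {
    sig <- max(unname(noise_sigmas[as.character(library$home_channels[[i]])]))
    sig / (sqrt(library$n_spikes[i]) * peak[i])
  }, numeric(1))

  parent <- uf_new(n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        chi <- as.character(library$home_channels[[i]])
        chj <- as.character(library$home_channels[[j]])
        # same electrode or neighboring electrodes
        if (min(pd[chi, chj]) >= thres_nb) next
        # the noise allowance is capped: the pair threshold may never reach
        # the scale at which genuinely different units sit (>= ~0.28)
        thr <- min(sqrt(merge_sigma^2 + 4 * k_dim * (s_t[i]^2 + s_t[j]^2)), 0.25)
        if (merge_distance(wn[i, ], wn[j, ], basis, max_lag) >= thr) next
        parent <- uf_union(parent, i, j)
      }
    }
  }
  comp <- uf_components(parent)

  merged <- lapply(sort(unique(comp)), function(g) {
    rows <- which(comp == g)
    wts <- if (weighted) library$n_spikes[rows] else rep(1L, length(rows))
    w <- do.call(rbind, library$waveform[rows])
    f <- do.call(rbind, library$feature_vector[rows])
    tibble::tibble(
      home_channels = list(sort(unique(unlist(library$home_channels[rows])))),
      n_spikes = sum(library$n_spikes[rows]),
      waveform = list(as.numeric(colSums(w * wts) / sum(wts))),
      feature_vector = list(as.numeric(colSums(f * wts) / sum(wts))),
      source_keys = list(sort(unique(unlist(library$source_keys[rows]))))
    )
  })
  out <- dplyr::bind_rows(merged)
  out <- dplyr::mutate(out, template_id = dplyr::row_number() - 1L)
  out <- dplyr::select(
    out, "template_id", "home_channels", "n_spikes", "waveform",
    "feature_vector", "source_keys"
  )
  class(out) <- c("ht_templates", class(out))
  for (a in c("snippet_length", "align_offset", "sampling_rate")) {
    attr(out, a) <- attr(library, a)
  }
  prov_keys <- unlist(out$source_keys)
  prov <- rep(out$template_id, vapply(out$source_keys, length, integer(1)))
  attr(out, "provenance") <- structure(prov, names = prov_keys)
  attr(out, "merge_sigma") <- merge_sigma
  # averaging can move two surviving templates within sigma of each other;
  # re-merge until the library is a fixed point
  if (nrow(out) < n) {
    again <- merge_templates(out, probe, merge_sigma, weighted, n_components,
      max_lag, noise_sigmas
    )
    if (nrow(again) < nrow(out)) return(again)
  }
  out
}
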