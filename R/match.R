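#' Similarity between a template and a segment window
#'
#' Normalized cross-correlation between the template and the segment window
#' starting at `lag`: `sum(T*I) / sqrt(sum(T^2) * sum(I^2))`. Dimensionless,
#' scale-invariant, bounded in `[-1, 1]`, maximal at a perfect match. The
#' alternative normalized squared-difference metric
#' `sum((T-I)^2) / sqrt(sum(T^2) * sum(I^2))` (minimal at a perfect match) is
#' available via `metric = "ssqdiff"`.
#'
#' @param segment Numeric voltage vector.
#' @param template Numeric template waveform (or an `ht_templates` row's
#'   waveform).
#' @param lag 0-based offset of the template window within the segment; the
#'   window must lie fully inside the segment.
#' @param metric `"ncc"` (default) or `"ssqdiff"`.
#' @return The similarity score; 0 when the template or the window carries no
#'   energy.
#' @export
spike_similarity <- function(segment, template, lag = 0, metric = c("ncc", "ssqdiff")) {
  metric <- match.arg(metric)
  L <- length(template)
  if (lag < 0 || lag + L > length(segment)) {
    abort("template window at this lag does not lie inside the segment")
  }
  win <- segment[(lag + 1):(lag + L)]
  et <- sum(template^2)
  ei <- sum(win^2)
  if (et == 0 || ei == 0) return(0)
  if (metric == "ncc") {
    sum(template * win) / sqrt(et * ei)
  } else {
    sum((template - win)^2) / sqrt(et * ei)
  }
}

#' Best-matching template over all admissible lags
#'
#' Exhaustive argmax of [spike_similarity()] over every template in the
#' library and every lag at which the template window fits inside the
#' segment. Ties break to the lower template id, then the earlier lag.
#'
#' @param segment Numeric voltage vector.
#' @param library An `ht_templates` tibble.
#' @param metric Matching metric, see [spike_similarity()].
#' @return A list `(template_id, lag, score)`; for `"ssqdiff"` the best score
#'   is the minimum.
#' @export
best_match <- function(segment, library, metric = c("ncc", "ssqdiff")) {
  metric <- match.arg(metric)
  if (nrow(library) == 0) abort("template library is empty")
  best <- NULL
  for (i in seq_len(nrow(library))) {
    tw <- library$waveform[[i]]
    L <- length(tw)
    lags <- 0:(length(segment) - L)
    if (length(lags) == 0 || lags[length(lags)] < 0) next
    scores <- vapply(lags, function(g) spike_similarity(segment, tw, g, metric), numeric(1))
    j <- if (metric == "ncc") which.max(scores) else which.min(scores)
    sc <- scores[j]
    better <- is.null(best) ||
      (if (metric == "ncc") sc > best$score else sc < best$score)
    if (better) {
      best <- list(template_id = library$template_id[i], lag = lags[j], score = sc, row = i)
    }
  }
  best
}

# all (template, lag) candidates ranked by least-squares energy gain,
# optionally requiring the match score to pass the acceptance level
rank_candidates <- function(residual, library, accept_threshold, metric,
                            require_accept = TRUE, top = Inf) {
  out <- list()
  for (i in seq_len(nrow(library))) {
    tw <- library$waveform[[i]]
    L <- length(tw)
    n_lag <- length(residual) - L + 1
    if (n_lag < 1) next
    et <- sum(tw^2)
    if (et == 0) next
    for (g in 0:(n_lag - 1)) {
      win <- residual[(g + 1):(g + L)]
      dot <- sum(tw * win)
      ei <- sum(win^2)
      if (ei == 0) next
      score <- if (metric == "ncc") dot / sqrt(et * ei) else sum((tw - win)^2) / sqrt(et * ei)
      ok <- if (metric == "ncc") score > accept_threshold else (1 - score) > accept_threshold
      if (require_accept && !ok) next
      out[[length(out) + 1L]] <- list(
        template_id = library$template_id[i], lag = g, score = score,
        row = i, gain = dot^2 / et
      )
    }
  }
  if (length(out) == 0) return(out)
  out <- out[order(-vapply(out, `[[`, numeric(1), "gain"))]
  head(out, top)
}

# joint two-atom refinement for deeply overlapping spikes: restore the stalled
# single-atom explanation, try pairs (c1 from the top energy candidates, c2
# found on the residual after c1), and keep the pair minimizing the joint
# least-squares residual — provided each atom passes the acceptance rule on
# the residual left by the other
rescue_pair <- function(residual0, library, accept_threshold, metric,
                        amp_min, scale_subtraction) {
  cands1 <- rank_candidates(residual0, library, accept_threshold, metric,
    require_accept = FALSE, top = 8
  )
  best <- NULL
  subtract <- function(res, cand) {
    tw <- library$waveform[[cand$row]]
    idx <- (cand$lag + 1):(cand$lag + length(tw))
    beta <- if (scale_subtraction) sum(tw * res[idx]) / sum(tw^2) else 1
    res[idx] <- res[idx] - beta * tw
    list(res = res, beta = beta, peak = max(abs(tw)) * abs(beta))
  }
  # re-fit one atom on the residual left by the other, scanning lags within
  # +/-3 of its current position (sequential fits bias the second lag)
  refit <- function(other_removed, cand) {
    tw <- library$waveform[[cand$row]]
    L <- length(tw)
    lags <- max(0, cand$lag - 3):min(length(other_removed) - L, cand$lag + 3)
    fit <- lapply(lags, function(g) {
      win <- other_removed[(g + 1):(g + L)]
      beta <- if (scale_subtraction) sum(tw * win) / sum(tw^2) else 1
      res <- other_removed
      res[(g + 1):(g + L)] <- win - beta * tw
      list(lag = g, beta = beta, rss = sum(res^2))
    })
    fit[[which.min(vapply(fit, `[[`, numeric(1), "rss"))]]
  }
  for (c1 in cands1) {
    s1 <- subtract(residual0, c1)
    c2 <- pick_candidate(s1$res, library, accept_threshold, metric)
    if (is.null(c2)) next
    a1 <- list(row = c1$row, template_id = c1$template_id, lag = c1$lag, beta = s1$beta)
    a2 <- list(row = c2$row, template_id = c2$template_id, lag = c2$lag, beta = NA)
    remove_atom <- function(a) {
      tw <- library$waveform[[a$row]]
      res <- residual0
      idx <- (a$lag + 1):(a$lag + length(tw))
      res[idx] <- res[idx] - a$beta * tw
      res
    }
    for (pass in 1:3) { # alternating joint refinement
      f2 <- refit(remove_atom(a1), a2)
      a2$lag <- f2$lag
      a2$beta <- f2$beta
      f1 <- refit(remove_atom(a2), a1)
      a1$lag <- f1$lag
      a1$beta <- f1$beta
    }
    r1_final <- remove_atom(a2)
    r2_final <- remove_atom(a1)
    sc1 <- spike_similarity(r1_final, library$waveform[[a1$row]], a1$lag, metric)
    sc2 <- spike_similarity(r2_final, library$waveform[[a2$row]], a2$lag, metric)
    ok <- if (metric == "ncc") {
      sc1 > accept_threshold && sc2 > accept_threshold
    } else {
      (1 - sc1) > accept_threshold && (1 - sc2) > accept_threshold
    }
    if (!ok) next
    pk1 <- abs(a1$beta) * max(abs(library$waveform[[a1$row]]))
    pk2 <- abs(a2$beta) * max(abs(library$waveform[[a2$row]]))
    if (amp_min > 0 && (pk1 < amp_min || pk2 < amp_min)) next
    resid <- r2_final
    idx2 <- (a2$lag + 1):(a2$lag + length(library$waveform[[a2$row]]))
    resid[idx2] <- resid[idx2] - a2$beta * library$waveform[[a2$row]]
    rss <- sum(resid^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(
        rss = rss, residual = resid,
        atoms = list(
          tibble::tibble(
            template_id = a1$template_id, lag = a1$lag, score = sc1,
            amplitude_scale = a1$beta
          ),
          tibble::tibble(
            template_id = a2$template_id, lag = a2$lag, score = sc2,
            amplitude_scale = a2$beta
          )
        )
      )
    }
  }
  best
}

# one pursuit step: among all (template, lag) candidates whose match score
# passes the acceptance level, take the one whose subtraction removes the
# most residual energy. Scoring the CHOICE by energy (not by normalized
# correlation) matters for deep overlaps: the correlation maximum of a
# two-spike mixture sits at a compromise lag between the constituents,
# whereas the energy criterion locks onto the constituent itself.
pick_candidate <- function(residual, library, accept_threshold, metric) {
  best <- NULL
  for (i in seq_len(nrow(library))) {
    tw <- library$waveform[[i]]
    L <- length(tw)
    n_lag <- length(residual) - L + 1
    if (n_lag < 1) next
    et <- sum(tw^2)
    if (et == 0) next
    for (g in 0:(n_lag - 1)) {
      win <- residual[(g + 1):(g + L)]
      dot <- sum(tw * win)
      ei <- sum(win^2)
      if (ei == 0) next
      score <- if (metric == "ncc") dot / sqrt(et * ei) else sum((tw - win)^2) / sqrt(et * ei)
      ok <- if (metric == "ncc") score > accept_threshold else (1 - score) > accept_threshold
      if (!ok) next
      gain <- dot^2 / et # residual energy removed by least-squares subtraction
      if (is.null(best) || gain > best$gain) {
        best <- list(
          template_id = library$template_id[i], lag = g, score = score,
          row = i, gain = gain
        )
      }
    }
  }
  best
}

#' Greedy template-matching pursuit on one segment
#'
#' Iterates: find the acceptable match (score above `accept_threshold`) whose
#' subtraction removes the most residual energy; subtract the
#' amplitude-scaled template (least-squares gain at the chosen lag, or the
#' raw template with `scale_subtraction = FALSE`) from the residual; repeat.
#' Stops when the residual peak falls below `dtc_th`, when the best candidate
#' is rejected, or at `max_iter` accepted spikes (the result is then flagged
#' `truncated`).
#'
#' @param segment Numeric voltage vector (an outlier event window).
#' @param library An `ht_templates` tibble.
#' @param accept_threshold Acceptance level on the match score.
#' @param dtc_th Residual amplitude stop level (voltage); conventionally the
#'   detection threshold of the segment's channel.
#' @param amp_min Minimum fitted spike amplitude (voltage) for acceptance; a
#'   candidate whose least-squares amplitude is below this is not a
#'   detectable spike but a chance correlation with smooth noise, and is
#'   rejected no matter its score. 0 disables the check.
#' @param max_iter Pursuit iteration cap.
#' @param scale_subtraction Subtract the least-squares-scaled template.
#' @param metric Matching metric, see [spike_similarity()].
#' @return A list of class `ht_match`: `accepted` (tibble with `template_id`,
#'   `lag`, `score`, `amplitude_scale`), `residual`, `n_iterations`,
#'   `truncated`.
#' @export
pursue <- function(segment, library, accept_threshold = 0.8, dtc_th,
                   amp_min = 0, max_iter = 5, scale_subtraction = TRUE,
                   metric = c("ncc", "ssqdiff")) {
  metric <- match.arg(metric)
  stopifnot(dtc_th > 0)
  residual <- segment
  accepted <- list()
  n_iter <- 0L
  truncated <- FALSE
  rescues <- 0L
  repeat {
    if (max(abs(residual)) < dtc_th) break # no spike-sized energy left
    if (length(accepted) >= max_iter) {
      truncated <- TRUE
      break
    }
    n_iter <- n_iter + 1L
    bm <- pick_candidate(residual, library, accept_threshold, metric)
    if (is.null(bm)) {
      # spike-sized energy remains but no single template is acceptable:
      # the last subtraction may have been a compromise fit across a deep
      # two-spike overlap — retry it as a joint pair
      if (length(accepted) >= 1 && rescues < 2L) {
        rescues <- rescues + 1L
        last <- accepted[[length(accepted)]]
        restored <- residual
        tw_last <- library$waveform[[match(last$template_id, library$template_id)]]
        idx_last <- (last$lag + 1):(last$lag + length(tw_last))
        restored[idx_last] <- restored[idx_last] + last$amplitude_scale * tw_last
        pair <- rescue_pair(restored, library, accept_threshold, metric,
          amp_min, scale_subtraction
        )
        if (!is.null(pair) && sum(pair$residual^2) < sum(residual^2)) {
          accepted[[length(accepted)]] <- pair$atoms[[1]]
          accepted[[length(accepted) + 1L]] <- pair$atoms[[2]]
          residual <- pair$residual
          next
        }
      }
      break
    }
    tw <- library$waveform[[bm$row]]
    idx <- (bm$lag + 1):(bm$lag + length(tw))
    beta <- if (scale_subtraction) sum(tw * residual[idx]) / sum(tw^2) else 1
    if (amp_min > 0 && abs(beta) * max(abs(tw)) < amp_min) break
    residual[idx] <- residual[idx] - beta * tw
    accepted[[length(accepted) + 1L]] <- tibble::tibble(
      template_id = bm$template_id, lag = bm$lag, score = bm$score,
      amplitude_scale = beta
    )
  }
  structure(
    list(
      accepted = if (length(accepted)) dplyr::bind_rows(accepted) else
        tibble::tibble(
          template_id = integer(0), lag = integer(0),
          score = numeric(0), amplitude_scale = numeric(0)
        ),
      residual = residual,
      n_iterations = max(n_iter, 1L),
      truncated = truncated
    ),
    class = "ht_match"
  )
}

#' Resolve outlier snippets by pursuit
#'
#' Every snippet labeled `-1` by the clustering stage (candidate overlapping
#' event, borderline detection, or noise) is re-examined: a segment of twice
#' the snippet length centered on its peak is cut from its channel's filtered
#' trace and pursued against the spatially admissible part of the template
#' library — templates homed on that channel or one of its probe neighbors.
#' (A spike cannot physically register on an electrode far from its unit, so
#' distant templates with coincidentally similar shapes are never
#' candidates.) Accepted spikes enter the output with the matched template's
#' unit label and an absolute peak time; outliers yielding no acceptable
#' match are discarded as noise.
#'
#' @param labeled Snippet tibble from [cluster_all()].
#' @param library Merged `ht_templates`.
#' @param rec The filtered `ht_recording` the snippets came from.
#' @param thresholds Named per-channel detection thresholds (used as the
#'   per-channel `dtc_th`).
#' @param noise_sigmas Named per-channel noise sigma estimates; with
#'   `min_snr > 0` the acceptance amplitude floor is
#'   `min_snr * noise_sigma[channel]`.
#' @param min_snr Amplitude floor multiplier (see [pursue()]'s `amp_min`).
#' @param accept_threshold,max_iter,scale_subtraction,metric See [pursue()].
#' @return A tibble of recovered spikes: `peak_index`, `unit`
#'   (template id), `score`, `source = "pursuit"`, `channel`.
#' @export
resolve_outliers <- function(labeled, library, rec, thresholds,
                             noise_sigmas = NULL, min_snr = 6,
                             accept_threshold = 0.8, max_iter = 5,
                             scale_subtraction = TRUE,
                             metric = c("ncc", "ssqdiff")) {
  metric <- match.arg(metric)
  empty <- tibble::tibble(
    peak_index = integer(0), unit = integer(0), score = numeric(0),
    source = character(0), channel = integer(0)
  )
  outliers <- labeled[labeled$label == -1L, , drop = FALSE]
  if (nrow(outliers) == 0 || nrow(library) == 0) return(empty)
  L <- attr(labeled, "snippet_length")
  off <- attr(labeled, "align_offset")
  n_samp <- ncol(rec$traces)
  chan_row <- match(outliers$channel, rec$probe$channel_id)

  # spatial gate: per channel, the templates homed on it or a neighbor
  pd <- probe_distances(rec$probe)
  thres_nb <- attr(rec$probe, "thres_nb")
  lib_for_channel <- lapply(as.character(rec$probe$channel_id), function(ch) {
    keep <- vapply(library$home_channels, function(hc) {
      min(pd[ch, as.character(hc)]) < thres_nb
    }, logical(1))
    library[keep, , drop = FALSE]
  })
  names(lib_for_channel) <- rec$probe$channel_id

  out <- vector("list", nrow(outliers))
  for (i in seq_len(nrow(outliers))) {
    ch <- as.character(outliers$channel[i])
    lib_i <- lib_for_channel[[ch]]
    if (nrow(lib_i) == 0) next
    pk <- outliers$peak_index[i]
    seg_start <- max(1L, pk - L) # segment spans ~2L centered on the peak
    seg_end <- min(n_samp, pk + L)
    segment <- rec$traces[chan_row[i], seg_start:seg_end]
    dtc <- unname(thresholds[ch])
    amp_min <- if (is.null(noise_sigmas)) 0 else min_snr * unname(noise_sigmas[ch])
    res <- pursue(segment, lib_i, accept_threshold, dtc,
      amp_min = amp_min, max_iter = max_iter,
      scale_subtraction = scale_subtraction, metric = metric
    )
    if (nrow(res$accepted) > 0) {
      out[[i]] <- dplyr::mutate(res$accepted,
        peak_index = seg_start + .data$lag + off,
        unit = .data$template_id,
        source = "pursuit",
        channel = outliers$channel[i]
      )
    }
  }
  got <- dplyr::bind_rows(out)
  if (nrow(got) == 0) return(empty)
  dplyr::select(got, "peak_index", "unit", "score", "source", "channel") |>
    dplyr::arrange(.data$peak_index)
}
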