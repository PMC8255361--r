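#' Classification metrics for sorted spikes
#'
#' `accuracy = tp / (tp + fp + fn)`, `precision = tp / (tp + fp)`,
#' `recall = tp / (tp + fn)`. A zero denominator yields 0. Note that
#' `accuracy <= min(precision, recall)` always holds.
#'
#' @param tp,fp,fn True positive, false positive, false negative counts.
#' @return A fraction in `[0, 1]`.
#' @export
accuracy <- function(tp, fp, fn) ifelse(tp + fp + fn > 0, tp / (tp + fp + fn), 0)

#' @rdname accuracy
#' @export
precision <- function(tp, fp) ifelse(tp + fp > 0, tp / (tp + fp), 0)

#' @rdname accuracy
#' @export
recall <- function(tp, fn) ifelse(tp + fn > 0, tp / (tp + fn), 0)

# greedy one-to-one pairing count between two sorted spike-time vectors
# within tol samples (two-pointer sweep)
pair_count <- function(a, b, tol) {
  i <- 1L; j <- 1L; n <- 0L
  while (i <= length(a) && j <= length(b)) {
    d <- a[i] - b[j]
    if (abs(d) <= tol) {
      n <- n + 1L; i <- i + 1L; j <- j + 1L
    } else if (d > 0) {
      j <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  n
}

#' Match sorted spikes against ground truth
#'
#' For every (ground-truth unit, sorter unit) pair, spikes are paired
#' greedily one-to-one within `tol_ms`. Each ground-truth unit is then
#' assigned at most one sorter unit, injectively, in descending order of the
#' pair's accuracy. Unassigned ground-truth units score `tp = 0`.
#'
#' @param gt_spikes Tibble with `time` (sample index) and `unit`.
#' @param sorted_spikes Tibble with `peak_index` (or `time`) and `unit`.
#' @param sampling_rate Hz.
#' @param tol_ms Pairing tolerance in milliseconds.
#' @return An `ht_evaluation`: tibble with one row per ground-truth unit
#'   (`gt_unit`, `sorter_unit`, `tp`, `fp`, `fn`, `accuracy`, `precision`,
#'   `recall`) plus attributes `n_sorter_units` and `tol_ms`.
#' @export
match_spikes <- function(gt_spikes, sorted_spikes, sampling_rate, tol_ms = 1.0) {
  tol <- tol_ms * sampling_rate / 1000
  stime <- sorted_spikes[["peak_index"]] %||% sorted_spikes[["time"]]
  sunit <- sorted_spikes$unit
  gt_units <- sort(unique(gt_spikes$unit))
  so_units <- sort(unique(sunit))

  gt_times <- lapply(gt_units, function(u) sort(gt_spikes$time[gt_spikes$unit == u]))
  so_times <- lapply(so_units, function(u) sort(stime[sunit == u]))

  pairs <- tidyr::expand_grid(gi = seq_along(gt_units), si = seq_along(so_units))
  if (nrow(pairs) > 0) {
    pairs$tp <- purrr::map2_int(
      pairs$gi, pairs$si,
      function(g, s) pair_count(gt_times[[g]], so_times[[s]], tol)
    )
    pairs$acc <- accuracy(
      pairs$tp,
      vapply(pairs$si, function(s) length(so_times[[s]]), integer(1)) - pairs$tp,
      vapply(pairs$gi, function(g) length(gt_times[[g]]), integer(1)) - pairs$tp
    )
    pairs <- dplyr::arrange(pairs, dplyr::desc(.data$acc), .data$gi, .data$si)
  }

  assigned_gt <- integer(0)
  assigned_so <- integer(0)
  take <- list()
  for (r in seq_len(nrow(pairs))) {
    g <- pairs$gi[r]; s <- pairs$si[r]
    if (g %in% assigned_gt || s %in% assigned_so || pairs$acc[r] <= 0) next
    assigned_gt <- c(assigned_gt, g)
    assigned_so <- c(assigned_so, s)
    take[[length(take) + 1L]] <- c(g = g, s = s, tp = pairs$tp[r])
  }

  rows <- lapply(seq_along(gt_units), function(g) {
    hit <- Filter(function(x) x["g"] == g, take)
    n_gt <- length(gt_times[[g]])
    if (length(hit) == 0) {
      tibble::tibble(
        gt_unit = gt_units[g], sorter_unit = NA_integer_,
        tp = 0L, fp = 0L, fn = n_gt
      )
    } else {
      h <- hit[[1]]
      tibble::tibble(
        gt_unit = gt_units[g],
        sorter_unit = so_units[h["s"]],
        tp = as.integer(h["tp"]),
        fp = length(so_times[[h["s"]]]) - as.integer(h["tp"]),
        fn = n_gt - as.integer(h["tp"])
      )
    }
  })
  out <- dplyr::bind_rows(rows)
  out$accuracy <- accuracy(out$tp, out$fp, out$fn)
  out$precision <- precision(out$tp, out$fp)
  out$recall <- recall(out$tp, out$fn)
  class(out) <- c("ht_evaluation", class(out))
  attr(out, "n_sorter_units") <- length(so_units)
  attr(out, "tol_ms") <- tol_ms
  out
}

#' Summarise an evaluation
#'
#' @param eval_tbl An `ht_evaluation` from [match_spikes()].
#' @return A one-row tibble: unweighted mean accuracy/precision/recall over
#'   ground-truth units, the ground-truth and detected unit counts, and total
#'   tp/fp/fn.
#' @export
report_evaluation <- function(eval_tbl) {
  tibble::tibble(
    n_gt_units = nrow(eval_tbl),
    n_sorter_units = attr(eval_tbl, "n_sorter_units"),
    mean_accuracy = mean(eval_tbl$accuracy),
    mean_precision = mean(eval_tbl$precision),
    mean_recall = mean(eval_tbl$recall),
    total_tp = sum(eval_tbl$tp),
    total_fp = sum(eval_tbl$fp),
    total_fn = sum(eval_tbl$fn)
  )
}

#' @export
tidy.ht_evaluation <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "ht_evaluation")
  out
}

#' @export
glance.ht_evaluation <- function(x, ...) report_evaluation(x)
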