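#' Principal-component feature space of a snippet group
#'
#' Fits a PCA on the group's waveforms and retains the leading components
#' (two by default: the first two components carry essentially all waveform
#' variance that sits above the noise floor, and a 2-D space keeps the density
#' clustering well conditioned).
#'
#' @param group A snippet tibble (one electrode group) with a `waveform` list
#'   column.
#' @param n_components Number of components to retain.
#' @return A list of class `ht_features`: `components` (L x n basis matrix,
#'   orthonormal columns), `projected` (n_snippets x n score matrix),
#'   `explained_variance_ratio`, `center`.
#' @export
fit_features <- function(group, n_components = 2) {
  w <- do.call(rbind, group$waveform)
  if (nrow(w) < n_components) {
    abort("group has fewer snippets than requested components")
  }
  pc <- prcomp(w, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$rotation))
  ev <- pc$sdev^2
  structure(
    list(
      components = pc$rotation[, seq_len(k), drop = FALSE],
      projected = pc$x[, seq_len(k), drop = FALSE],
      explained_variance_ratio = if (sum(ev) > 0) ev[seq_len(k)] / sum(ev) else rep(0, k),
      center = pc$center
    ),
    class = "ht_features"
  )
}

#' Cluster one group's feature space
#'
#' Runs [hdbscan()] on the projected features. Outliers (label `-1`) are
#' candidate overlapping events or background noise and are passed on to
#' template-matching pursuit instead of contaminating templates.
#'
#' @param features An [fit_features()] result, or a numeric matrix of feature
#'   coordinates.
#' @param min_cluster_size,min_samples Density clustering controls.
#' @return An `ht_hdbscan` labeling (`labels`, `n_clusters`, `cluster_sizes`).
#' @export
cluster_group <- function(features, min_cluster_size = 10, min_samples = 5) {
  x <- if (inherits(features, "ht_features")) features$projected else as.matrix(features)
  hdbscan(x, min_cluster_size = min_cluster_size, min_samples = min_samples)
}

#' Cluster every electrode group
#'
#' Fits per-group features and labels each group independently (results do
#' not depend on group order, and serial or parallel execution would give
#' identical output). Groups with fewer snippets than `min_cluster_size`
#' cannot support a template and are labeled entirely as outliers.
#'
#' @param groups Named list of snippet tibbles from [build_groups()].
#' @param n_components PCA components per group.
#' @param min_cluster_size,min_samples Density clustering controls.
#' @return A tibble: all retained snippets with columns `pc1`, `pc2`, `label`
#'   (per-group cluster label, `-1` = outlier) and `cluster_key`
#'   (`"<channel>:<label>"`, `NA` for outliers).
#' @export
cluster_all <- function(groups, n_components = 2, min_cluster_size = 10,
                        min_samples = 5) {
  labeled <- lapply(groups, function(g) {
    n <- nrow(g)
    if (n < max(min_cluster_size, n_components)) {
      g$pc1 <- NA_real_
      g$pc2 <- NA_real_
      g$label <- -1L
      return(g)
    }
    fs <- fit_features(g, n_components)
    lab <- cluster_group(fs, min_cluster_size, min_samples)
    g$pc1 <- fs$projected[, 1]
    g$pc2 <- if (ncol(fs$projected) >= 2) fs$projected[, 2] else NA_real_
    g$label <- lab$labels
    g
  })
  out <- dplyr::bind_rows(labeled)
  out$cluster_key <- ifelse(out$label >= 0,
    paste0(out$channel, ":", out$label), NA_character_
  )
  for (a in c("snippet_length", "align_offset", "sampling_rate")) {
    attr(out, a) <- attr(groups[[1]], a)
  }
  out
}
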