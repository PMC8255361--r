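#' Probe geometry
#'
#' A probe geometry is a tibble with one row per recording channel: an integer
#' `channel_id` and 2-D coordinates `x`, `y` in micrometres. The neighbor
#' radius `thres_nb` (micrometres) is carried as an attribute: channels `a != b`
#' are neighbors iff their Euclidean distance is strictly less than `thres_nb`.
#' Neighborhood gates both duplicate-spike coalescing and template merging.
#'
#' @param channel_ids Integer channel labels (unique).
#' @param positions Numeric matrix or data frame with one `(x, y)` row per
#'   channel, in micrometres.
#' @param thres_nb Neighbor radius in micrometres. Any positive value is
#'   accepted; values outside the conventional 20--50 um range raise a warning.
#' @return A tibble of class `ht_probe` with columns `channel_id`, `x`, `y`.
#' @examples
#' probe_geometry(0:3, cbind(0, c(0, 25, 50, 75)))
#' @export
probe_geometry <- function(channel_ids, positions, thres_nb = 40) {
  channel_ids <- as.integer(channel_ids)
  if (anyDuplicated(channel_ids)) abort("channel_ids must be unique")
  positions <- as.matrix(positions)
  if (nrow(positions) != length(channel_ids) || ncol(positions) != 2) {
    abort("positions must supply exactly one (x, y) pair per channel_id")
  }
  if (!all(is.finite(positions))) abort("probe positions must all be finite")
  if (!is.numeric(thres_nb) || length(thres_nb) != 1 || thres_nb <= 0) {
    abort("thres_nb must be a single positive length in micrometres")
  }
  if (thres_nb < 20 || thres_nb > 50) {
    warn(sprintf("thres_nb = %g um is outside the conventional 20-50 um range", thres_nb))
  }
  probe <- tibble::tibble(
    channel_id = channel_ids,
    x = as.numeric(positions[, 1]),
    y = as.numeric(positions[, 2])
  )
  attr(probe, "thres_nb") <- as.numeric(thres_nb)
  class(probe) <- c("ht_probe", class(probe))
  probe
}

#' Neighbor relation of a probe
#'
#' @param probe An [probe_geometry()] tibble.
#' @param thres_nb Optional override of the probe's neighbor radius (um).
#' @return A symmetric logical matrix with `FALSE` diagonal, dimnames the
#'   channel ids; `[a, b]` is `TRUE` iff channels a and b are neighbors.
#' @export
probe_neighbors <- function(probe, thres_nb = NULL) {
  thres_nb <- thres_nb %||% attr(probe, "thres_nb")
  d <- as.matrix(stats::dist(cbind(probe$x, probe$y)))
  nb <- d < thres_nb
  diag(nb) <- FALSE
  dimnames(nb) <- list(probe$channel_id, probe$channel_id)
  nb
}

#' Pairwise channel distances in micrometres
#' @param probe An [probe_geometry()] tibble.
#' @return Symmetric numeric matrix with channel-id dimnames.
#' @export
probe_distances <- function(probe) {
  d <- as.matrix(stats::dist(cbind(probe$x, probe$y)))
  dimnames(d) <- list(probe$channel_id, probe$channel_id)
  d
}

#' Read and write probe geometry as JSON
#'
#' The native probe file is a small JSON document with fields `channel_ids`,
#' `positions_um` (n x 2 array) and `thres_nb`.
#'
#' @param path File path.
#' @return `read_probe()` returns an `ht_probe`; `write_probe()` returns
#'   `path` invisibly.
#' @export
read_probe <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("channel_ids", "positions_um")) {
    if (is.null(doc[[f]])) abort(sprintf("probe file is missing field '%s'", f))
  }
  probe_geometry(doc$channel_ids, doc$positions_um, thres_nb = doc$thres_nb %||% 40)
}

#' @rdname read_probe
#' @param probe An `ht_probe`.
#' @export
write_probe <- function(probe, path) {
  jsonlite::write_json(
    list(
      channel_ids = probe$channel_id,
      positions_um = cbind(probe$x, probe$y),
      thres_nb = attr(probe, "thres_nb")
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a PRB-style geometry mapping (convenience)
#'
#' Best-effort reader for the common PRB probe dialect: extracts the
#' `channel_positions`-like mapping of `id: [x, y]` pairs with a tolerant
#' line-based parse. Only the geometry is read; grouping/graph entries are
#' ignored.
#'
#' @param path Path to a PRB-style file.
#' @param thres_nb Neighbor radius to attach (um).
#' @return An `ht_probe`.
#' @export
read_probe_prb <- function(path, thres_nb = 40) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  # match entries of the form  <id> : [ <x> , <y> ]  (PRB geometry dicts)
  m <- gregexpr("(\\d+)\\s*:\\s*[\\[(]\\s*(-?[0-9.eE+]+)\\s*,\\s*(-?[0-9.eE+]+)\\s*[\\])]", txt, perl = TRUE)
  hits <- regmatches(txt, m)[[1]]
  if (length(hits) == 0) abort("no channel-position entries found in PRB file")
  parse_one <- function(h) {
    nums <- regmatches(h, gregexpr("-?[0-9.eE+]+", h))[[1]]
    as.numeric(nums[1:3])
  }
  tab <- do.call(rbind, lapply(hits, parse_one))
  tab <- tab[!duplicated(tab[, 1]), , drop = FALSE]
  tab <- tab[order(tab[, 1]), , drop = FALSE]
  probe_geometry(tab[, 1], tab[, 2:3], thres_nb = thres_nb)
}

#' Construct a regular probe layout
#'
#' Deterministic synthetic probe geometries: a single line of contacts
#' (`"linear"`) or a staggered two-column arrangement (`"two-column"`)
#' mimicking dense silicon probes.
#'
#' @param n_channels Number of contacts.
#' @param pitch_um Contact pitch in micrometres.
#' @param layout `"linear"` or `"two-column"`.
#' @param thres_nb Neighbor radius in micrometres.
#' @return An `ht_probe` with channel ids `0:(n_channels-1)`.
#' @examples
#' make_probe(4, 25, "linear")
#' @export
make_probe <- function(n_channels, pitch_um = 25, layout = c("linear", "two-column"),
                       thres_nb = 40) {
  layout <- match.arg(layout)
  stopifnot(n_channels >= 1, pitch_um > 0)
  idx <- seq_len(n_channels) - 1L
  if (layout == "linear") {
    pos <- cbind(rep(0, n_channels), idx * pitch_um)
  } else {
    col <- idx %% 2L
    row <- idx %/% 2L
    # stagger the second column by half a pitch so all pairwise gaps >= pitch
    pos <- cbind(col * pitch_um, row * pitch_um + col * pitch_um / 2)
  }
  probe_geometry(idx, pos, thres_nb = thres_nb)
}
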