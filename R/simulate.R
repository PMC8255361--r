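# evaluate code under a temporary RNG state so generator calls do not disturb
# the caller's random stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic ground-truth recording
#'
#' Describes a desk-scale extracellular recording with the statistical
#' structure the sorting pipeline assumes: biphasic spike templates whose
#' per-channel amplitude decays exponentially with distance from the unit,
#' Poisson spike trains with an absolute refractory period, a controllable
#' fraction of temporally colliding spikes, and additive Gaussian background
#' noise. The seed fully determines the output.
#'
#' @param n_channels,n_units,duration_s Recording shape.
#' @param sampling_rate_hz Working sampling rate of the rendered traces.
#' @param probe_pitch_um,probe_layout Probe geometry (see [make_probe()]).
#' @param noise_sigma Background noise standard deviation (voltage units).
#' @param snr Peak template amplitude on the best channel, in units of
#'   `noise_sigma`.
#' @param firing_rate_hz Mean firing rate per unit.
#' @param refractory_ms Absolute refractory period.
#' @param collision_fraction Fraction of spikes re-timed onto another unit's
#'   spike to create controlled overlaps, in `[0, 1)`.
#' @param decay_constant_um Spatial decay length of spike amplitude over the
#'   probe; with a 25--40 um pitch each spike is seen on 2--4 contacts.
#' @param placement `"near-electrode"` jitters each unit around a distinct
#'   contact (sortable units sit close to a recording site); `"midway"`
#'   places units halfway between vertically adjacent contacts (the
#'   best-channel-flipping regime that exercises template merging);
#'   `"uniform"` scatters them over the probe's bounding box.
#' @param position_jitter_um Radius of the placement jitter for
#'   `"near-electrode"`.
#' @param seed Integer seed.
#' @return A list of class `ht_sim_spec`.
#' @export
simulation_spec <- function(n_channels = 32, n_units = 10, duration_s = 30,
                            sampling_rate_hz = 14000, probe_pitch_um = 25,
                            probe_layout = "two-column", noise_sigma = 10,
                            snr = 10, firing_rate_hz = 5, refractory_ms = 2,
                            collision_fraction = 0, decay_constant_um = 30,
                            placement = c("near-electrode", "midway", "uniform"),
                            position_jitter_um = 6, seed = 1) {
  placement <- match.arg(placement)
  spec <- list(
    n_channels = n_channels, n_units = n_units, duration_s = duration_s,
    sampling_rate_hz = sampling_rate_hz, probe_pitch_um = probe_pitch_um,
    probe_layout = probe_layout, noise_sigma = noise_sigma, snr = snr,
    firing_rate_hz = firing_rate_hz, refractory_ms = refractory_ms,
    collision_fraction = collision_fraction,
    decay_constant_um = decay_constant_um, placement = placement,
    position_jitter_um = position_jitter_um, seed = as.integer(seed)
  )
  num <- spec[!(names(spec) %in% c("probe_layout", "placement"))]
  if (!all(vapply(num, function(v) is.numeric(v) && length(v) == 1, logical(1)))) {
    abort("all numeric simulation fields must be scalars")
  }
  if (collision_fraction < 0 || collision_fraction >= 1) {
    abort("collision_fraction must lie in [0, 1)")
  }
  must_pos <- setdiff(names(num), c("collision_fraction", "seed"))
  if (any(unlist(num[must_pos]) <= 0)) {
    abort("all simulation quantities except collision_fraction must be positive")
  }
  structure(spec, class = "ht_sim_spec")
}

#' Ground-truth unit templates
#'
#' Each unit receives a biphasic canonical waveform — a sharp negative trough
#' followed by a slower positive overshoot, built from a difference of gamma
#' kernels with randomized width and asymmetry — and a 2-D position on the
#' probe. The waveform's amplitude on channel `c` is
#' `snr * noise_sigma * exp(-distance(unit, c) / decay_constant_um)`.
#'
#' @param spec An [simulation_spec()].
#' @param probe Optional probe (defaults to the spec's [make_probe()]).
#' @return A tibble with one row per unit: `unit`, `x`, `y`, `best_channel`,
#'   `peak_amplitude`, `waveform` (list, peak-normalized, `peak_offset`
#'   attribute), `channel_amplitudes` (list, one gain per channel).
#' @export
make_unit_templates <- function(spec, probe = NULL) {
  probe <- probe %||% make_probe(spec$n_channels, spec$probe_pitch_um, spec$probe_layout)
  fs <- spec$sampling_rate_hz
  with_seed(spec$seed + 1L, {
    pos <- unit_positions(spec, probe)
    rows <- lapply(seq_len(spec$n_units), function(u) {
      w <- biphasic_waveform(fs)
      d <- sqrt((probe$x - pos$x[u])^2 + (probe$y - pos$y[u])^2)
      # exponential decay over distance, scaled so the best (nearest) channel
      # carries exactly snr * noise_sigma — SNR is defined at the best channel
      amps <- exp(-d / spec$decay_constant_um)
      amps <- spec$snr * spec$noise_sigma * amps / max(amps)
      tibble::tibble(
        unit = u, x = pos$x[u], y = pos$y[u],
        best_channel = probe$channel_id[which.max(amps)],
        peak_amplitude = max(amps),
        waveform = list(w),
        channel_amplitudes = list(structure(amps, names = probe$channel_id))
      )
    })
    dplyr::bind_rows(rows)
  })
}

# greedy max-min packing: random first point, every next point maximizes its
# minimum distance to those already chosen
farthest_point_pick <- function(points, K) {
  chosen <- sample(nrow(points), 1)
  while (length(chosen) < K) {
    dmin <- vapply(seq_len(nrow(points)), function(i) {
      min(sqrt((points[chosen, 1] - points[i, 1])^2 +
        (points[chosen, 2] - points[i, 2])^2))
    }, numeric(1))
    dmin[chosen] <- -Inf
    chosen <- c(chosen, which.max(dmin))
  }
  chosen
}

unit_positions <- function(spec, probe) {
  K <- spec$n_units
  if (K > nrow(probe)) abort("need at least as many channels as units")
  switch(spec$placement,
    "near-electrode" = {
      home <- farthest_point_pick(cbind(probe$x, probe$y), K)
      ang <- runif(K, 0, 2 * pi)
      rad <- spec$position_jitter_um * sqrt(runif(K))
      list(x = probe$x[home] + rad * cos(ang), y = probe$y[home] + rad * sin(ang))
    },
    "midway" = {
      # halfway between a contact and its nearest vertical neighbor; units are
      # kept >= 2 * thres_nb apart (well-separated boundary units), sampling
      # home contacts until the spacing holds
      pd <- probe_distances(probe)
      thres_nb <- attr(probe, "thres_nb")
      midpoint <- function(home) {
        mate <- vapply(home, function(i) {
          same_col <- which(probe$x == probe$x[i] & seq_len(nrow(probe)) != i)
          same_col[which.min(pd[i, same_col])]
        }, integer(1))
        cbind(
          (probe$x[home] + probe$x[mate]) / 2,
          (probe$y[home] + probe$y[mate]) / 2
        )
      }
      # greedy farthest-point choice over all candidate midpoints: random
      # 6-subsets almost never reach well-separated spacing on a dense
      # probe, the greedy packing reliably does
      cand <- midpoint(seq_len(nrow(probe)))
      chosen <- farthest_point_pick(cand, K)
      list(x = cand[chosen, 1], y = cand[chosen, 2])
    },
    "uniform" = list(
      x = runif(K, min(probe$x), max(probe$x)),
      y = runif(K, min(probe$y), max(probe$y))
    )
  )
}

# biphasic spike shape: negative gamma-kernel trough, delayed positive
# overshoot; peak-normalized, ~2 ms support
biphasic_waveform <- function(fs, len_ms = 2) {
  tt <- seq(0, len_ms, by = 1000 / fs) # ms
  # parameter ranges span the trough-width / overshoot variety seen across
  # cortical cell types (narrow fast-spiking to broad regular-spiking)
  s1 <- runif(1, 0.05, 0.15)
  s2 <- runif(1, 0.15, 0.45)
  delay <- runif(1, 0.08, 0.35)
  ratio <- runif(1, 0.2, 0.6)
  onset <- 0.3 # ms of flat lead-in so the trough is interior
  t1 <- pmax(tt - onset, 0)
  g1 <- stats::dgamma(t1, shape = 2, scale = s1)
  # the positive overshoot starts past the trough so both lobes stay visible
  g2 <- stats::dgamma(pmax(t1 - (2 * s1 + delay), 0), shape = 2, scale = s2)
  w <- -g1 / max(g1) + ratio * g2 / max(g2)
  w <- w / max(abs(w))
  structure(w, peak_offset = which.max(abs(w)) - 1L)
}

#' Ground-truth spike trains
#'
#' Per-unit stationary Poisson trains with an absolute refractory period
#' (dead time added to exponential intervals). When `collision_fraction > 0`,
#' that fraction of spikes is re-timed to land within half a spike width of a
#' randomly chosen spike of another unit, creating controlled overlapping
#' events; a re-timing that would violate the unit's own refractory period is
#' abandoned.
#'
#' @param spec An [simulation_spec()].
#' @return A tibble sorted by `time` (sample index): `time`, `unit`,
#'   `is_collision`.
#' @export
make_spike_trains <- function(spec) {
  fs <- spec$sampling_rate_hz
  n_samp <- round(spec$duration_s * fs)
  refr <- spec$refractory_ms / 1000
  margin <- snippet_length(3, fs) # keep windows clear of the edges
  with_seed(spec$seed + 2L, {
    trains <- lapply(seq_len(spec$n_units), function(u) {
      t <- numeric(0)
      cur <- 0
      repeat {
        cur <- cur + refr + rexp(1, spec$firing_rate_hz)
        if (cur >= spec$duration_s) break
        t <- c(t, cur)
      }
      tibble::tibble(time = round(t * fs), unit = u)
    })
    spikes <- dplyr::bind_rows(trains)
    spikes <- spikes[spikes$time > margin & spikes$time < n_samp - margin, ]
    spikes$is_collision <- FALSE
    if (spec$collision_fraction > 0 && nrow(spikes) > 1) {
      half_width <- round(1e-3 * fs) # half of the ~2 ms spike support
      n_coll <- floor(spec$collision_fraction * nrow(spikes))
      victims <- sample(seq_len(nrow(spikes)), n_coll)
      for (v in victims) {
        # a collision partner must keep its own timing: never pair with a
        # spike that is itself scheduled for re-timing
        others <- which(spikes$unit != spikes$unit[v] & !spikes$is_collision &
          !(seq_len(nrow(spikes)) %in% victims))
        if (length(others) == 0) next
        tgt <- others[sample.int(length(others), 1)]
        new_t <- spikes$time[tgt] + sample(seq(-half_width, half_width), 1)
        if (new_t <= margin || new_t >= n_samp - margin) next
        own <- spikes$time[spikes$unit == spikes$unit[v]]
        own <- own[own != spikes$time[v]]
        if (length(own) > 0 && min(abs(own - new_t)) < refr * fs) next
        spikes$time[v] <- new_t
        spikes$is_collision[v] <- TRUE
        spikes$is_collision[tgt] <- TRUE
      }
    }
    dplyr::arrange(spikes, .data$time, .data$unit)
  })
}

#' Render a synthetic recording with ground truth
#'
#' Superimposes every unit's per-channel waveform at its spike times (the
#' waveform trough lands exactly on the spike's sample time) and adds i.i.d.
#' Gaussian noise of standard deviation `noise_sigma`. Fully reproducible
#' from the spec's seed.
#'
#' @param spec An [simulation_spec()].
#' @return A list of class `ht_simulation`: `recording` (an `ht_recording`),
#'   `truth` (list with `spikes`, `units`, and the probe), `spec`.
#' @export
render_recording <- function(spec) {
  probe <- make_probe(spec$n_channels, spec$probe_pitch_um, spec$probe_layout)
  units <- make_unit_templates(spec, probe)
  spikes <- make_spike_trains(spec)
  fs <- spec$sampling_rate_hz
  n_samp <- round(spec$duration_s * fs)
  traces <- matrix(0, nrow(probe), n_samp)
  for (u in seq_len(nrow(units))) {
    w <- units$waveform[[u]]
    pk <- attr(w, "peak_offset")
    amps <- units$channel_amplitudes[[u]]
    active <- which(amps >= 0.02 * max(amps))
    st <- spikes$time[spikes$unit == units$unit[u]]
    for (t in st) {
      idx <- (t - pk):(t - pk + length(w) - 1L)
      ok <- idx >= 1 & idx <= n_samp
      for (c in active) {
        traces[c, idx[ok]] <- traces[c, idx[ok]] + amps[c] * w[ok]
      }
    }
  }
  if (spec$noise_sigma > 0) {
    with_seed(spec$seed + 3L, {
      traces <- traces + matrix(
        rnorm(length(traces), sd = spec$noise_sigma), nrow(traces)
      )
    })
  }
  structure(
    list(
      recording = recording(traces, fs, probe),
      truth = list(spikes = spikes, units = units, probe = probe),
      spec = spec
    ),
    class = "ht_simulation"
  )
}

#' @export
print.ht_simulation <- function(x, ...) {
  cat(sprintf(
    "<ht_simulation> %d units on %d channels, %g s @ %g Hz, %d spikes (%d in collisions)\n",
    x$spec$n_units, x$spec$n_channels, x$spec$duration_s,
    x$spec$sampling_rate_hz, nrow(x$truth$spikes), sum(x$truth$spikes$is_collision)
  ))
  invisible(x)
}
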