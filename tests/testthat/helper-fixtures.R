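# shared fixtures; heavyweight simulations are built once per test run
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a small two-column probe
test_probe <- function(n = 8, pitch = 25, thres_nb = 40) {
  make_probe(n, pitch, "two-column", thres_nb = thres_nb)
}

# a single biphasic test waveform with peak at `peak_at` (1-based), length L
test_spike_wave <- function(L = 42, peak_at = 22, trough_w = 3, ratio = 0.4) {
  t <- seq_len(L) - peak_at
  w <- -exp(-(t / trough_w)^2) + ratio * exp(-((t - 3 * trough_w) / (2 * trough_w))^2)
  w / max(abs(w))
}

# snippet tibble builder for unit tests of grouping/clustering/templates
make_snippets <- function(channel, peak_index, waveforms, sampling_rate = 14000,
                          L = length(waveforms[[1]]), align_offset = floor(L / 2)) {
  out <- tibble::tibble(
    channel = as.integer(channel),
    peak_index = as.integer(peak_index),
    peak_amplitude = vapply(waveforms, function(w) max(abs(w)), numeric(1)),
    waveform = waveforms
  )
  attr(out, "snippet_length") <- L
  attr(out, "align_offset") <- align_offset
  attr(out, "sampling_rate") <- sampling_rate
  out
}

# medium ground-truth recording shared by pipeline-level tests
small_sim <- function() {
  cached("small_sim", render_recording(simulation_spec(
    n_channels = 8, n_units = 3, duration_s = 10, seed = 42
  )))
}

small_run <- function() {
  cached("small_run", run_pipeline(small_sim()$recording))
}
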