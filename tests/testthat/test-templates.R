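labeled_from <- function(channel, waveforms, labels) {
  out <- make_snippets(channel, seq_along(channel) * 200, waveforms)
  out$label <- as.integer(labels)
  out$cluster_key <- ifelse(out$label >= 0, paste0(out$channel, ":", out$label), NA)
  out
}

test_that("templates are pointwise means of their member snippets", {
  w <- test_spike_wave()
  one <- labeled_from(0L, list(3 * w), 0)
  lib1 <- estimate_templates(one)
  expect_equal(lib1$waveform[[1]], 3 * w)
  expect_equal(lib1$n_spikes, 1L)
  expect_equal(lib1$home_channels[[1]], 0L)

  anti <- labeled_from(c(0L, 0L), list(w, -w), c(0, 0))
  expect_equal(estimate_templates(anti)$waveform[[1]], 0 * w)

  set.seed(4)
  truth <- 5 * test_spike_wave()
  copies <- lapply(1:50, function(i) truth + rnorm(length(truth), sd = 1)) # SNR 5
  lib <- estimate_templates(labeled_from(rep(2L, 50), copies, rep(0, 50)))
  expect_gt(stats::cor(lib$waveform[[1]], truth), 0.99)

  expect_equal(nrow(estimate_templates(labeled_from(0L, list(w), -1))), 0)
})

test_that("shared space is scale-free and separates dissimilar shapes", {
  w <- test_spike_wave()
  v <- test_spike_wave(trough_w = 8, ratio = 0.6)
  u <- rev(w)
  lib <- estimate_templates(labeled_from(
    c(0L, 1L, 2L, 3L), list(w, 2 * w, v, u), rep(0, 4)
  ))
  lib <- build_shared_space(lib)
  fv <- do.call(rbind, lib$feature_vector)
  expect_equal(sqrt(sum((fv[1, ] - fv[2, ])^2)), 0, tolerance = 1e-9) # w vs 2w
  expect_gt(sqrt(sum((fv[1, ] - fv[3, ])^2)), 0.05)
  # cosine similarity between w and v is moderate: distance must exceed 0.05
  expect_lt(sum(w * v) / sqrt(sum(w^2) * sum(v^2)), 0.9)
})

test_that("sub-threshold templates are screened into the outlier pool", {
  w <- test_spike_wave()
  lab <- labeled_from(
    c(rep(0L, 3), rep(1L, 3)),
    c(lapply(1:3, function(i) 10 * w), lapply(1:3, function(i) 2 * w)),
    c(0, 0, 0, 0, 0, 0)
  )
  sig <- c("0" = 1, "1" = 1)
  scr <- screen_templates(estimate_templates(lab), lab, sig, min_snr = 5)
  expect_equal(nrow(scr$library), 1)
  expect_equal(scr$library$home_channels[[1]], 0L)
  expect_true(all(scr$labeled$label[scr$labeled$channel == 1] == -1L))
  expect_true(all(is.na(scr$labeled$cluster_key[scr$labeled$channel == 1])))
})

test_that("merging requires both shape similarity and spatial adjacency", {
  probe <- make_probe(6, 25, "linear", thres_nb = 30) # adjacent only
  w <- test_spike_wave()
  # identical templates on neighboring channels collapse to one
  nb_lib <- build_shared_space(estimate_templates(labeled_from(
    c(0L, 1L, 3L), list(10 * w, 10 * w, 10 * rev(w)), rep(0, 3)
  )))
  merged <- merge_templates(nb_lib, probe, merge_sigma = 0.05)
  expect_equal(nrow(merged), 2)
  prov <- attr(merged, "provenance")
  expect_equal(unname(prov["0:0"]), unname(prov["1:0"]))

  # identical templates on non-neighbor channels stay apart
  far_lib <- build_shared_space(estimate_templates(labeled_from(
    c(0L, 3L, 5L), list(10 * w, 10 * w, 10 * rev(w)), rep(0, 3)
  )))
  expect_equal(nrow(merge_templates(far_lib, probe, merge_sigma = 0.05)), 3)
})

test_that("the merge threshold separates pairs straddling sigma", {
  probe <- make_probe(4, 25, "linear")
  base <- test_spike_wave()
  bump <- test_spike_wave(trough_w = 10, ratio = 0.1) # a second shape direction
  make_lib <- function(eps) {
    build_shared_space(estimate_templates(labeled_from(
      c(0L, 1L, 2L, 3L),
      list(10 * base, 10 * (base * (1 - eps) + eps * bump), 10 * bump, 10 * rev(base)),
      rep(0, 4)
    )))
  }
  # independent distance oracle: PCA projection of the peak-normalized
  # waveforms computed directly in the test
  pair_distance <- function(lib) {
    w <- do.call(rbind, lib$waveform)
    wn <- w / apply(abs(w), 1, max)
    sc <- prcomp(wn, center = TRUE)$x[, 1:min(5, nrow(wn) - 1)]
    sqrt(sum((sc[1, ] - sc[2, ])^2))
  }
  # choose perturbations that land below and above sigma = 0.05
  eps_small <- 0.005
  eps_big <- 0.05
  d_small <- pair_distance(make_lib(eps_small))
  d_big <- pair_distance(make_lib(eps_big))
  expect_lt(d_small, 0.05)
  expect_gt(d_big, 0.05)
  expect_equal(nrow(merge_templates(make_lib(eps_small), probe, merge_sigma = 0.05)), 3)
  expect_equal(nrow(merge_templates(make_lib(eps_big), probe, merge_sigma = 0.05)), 4)
})

test_that("merging is idempotent and order-independent", {
  probe <- make_probe(8, 25, "two-column")
  set.seed(12)
  shapes <- list(
    test_spike_wave(), test_spike_wave(trough_w = 5, ratio = 0.3),
    test_spike_wave(trough_w = 8, ratio = 0.6), rev(test_spike_wave())
  )
  chans <- c(0L, 1L, 2L, 4L, 5L, 7L)
  wf <- lapply(seq_along(chans), function(i) {
    10 * shapes[[(i - 1) %% 4 + 1]] + rnorm(42, sd = 0.05)
  })
  lib <- build_shared_space(estimate_templates(labeled_from(chans, wf, rep(0, 6))))
  m1 <- merge_templates(lib, probe)
  m2 <- merge_templates(m1, probe)
  expect_equal(nrow(m2), nrow(m1))
  expect_equal(m2$waveform, m1$waveform)

  perm <- c(4, 2, 6, 1, 5, 3)
  libp <- lib[perm, , drop = FALSE]
  class(libp) <- class(lib)
  for (a in c("snippet_length", "align_offset", "sampling_rate", "shared_basis")) {
    attr(libp, a) <- attr(lib, a)
  }
  mp <- merge_templates(libp, probe)
  part <- function(m) sort(vapply(m$source_keys, function(k) paste(sort(k), collapse = "+"), ""))
  expect_equal(part(mp), part(m1))
})

test_that("spike-count weighting protects well-supported templates", {
  probe <- make_probe(2, 25, "linear")
  w <- test_spike_wave()
  v <- w + 0.02 * rev(w)
  lab <- labeled_from(
    c(rep(0L, 5), 1L),
    c(lapply(1:5, function(i) 10 * w), list(10 * v)),
    c(rep(0, 5), 0)
  )
  lib <- build_shared_space(estimate_templates(lab))
  mw <- merge_templates(lib, probe, merge_sigma = 0.3, weighted = TRUE)
  mu <- merge_templates(lib, probe, merge_sigma = 0.3, weighted = FALSE)
  expect_equal(nrow(mw), 1)
  expect_equal(mw$waveform[[1]], (5 * 10 * w + 10 * v) / 6)
  expect_equal(mu$waveform[[1]], (10 * w + 10 * v) / 2)
})
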