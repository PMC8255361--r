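tiny_library <- function(waveforms) {
  lib <- tibble::tibble(
    template_id = seq_along(waveforms) - 1L,
    home_channels = lapply(waveforms, function(w) 0L),
    n_spikes = rep(50L, length(waveforms)),
    waveform = waveforms,
    source_keys = lapply(seq_along(waveforms), function(i) paste0("0:", i - 1))
  )
  class(lib) <- c("ht_templates", class(lib))
  lib
}

test_that("similarity is a normalized, scale-invariant correlation", {
  w <- 10 * test_spike_wave()
  expect_equal(spike_similarity(w, w), 1.0)
  expect_equal(spike_similarity(-w, w), -1.0)
  expect_equal(spike_similarity(3.7 * w, w), 1.0)
  expect_equal(spike_similarity(rep(0, length(w)), w), 0)
  expect_equal(spike_similarity(w, rep(0, length(w))), 0)
  expect_error(spike_similarity(w[1:10], w), "inside the segment")

  # squared-difference form: 0 at a perfect match, grows with mismatch
  expect_equal(spike_similarity(w, w, metric = "ssqdiff"), 0)
  expect_gt(spike_similarity(-w, w, metric = "ssqdiff"), 1)
})

test_that("best_match scans all templates and lags with stable tie-breaks", {
  w1 <- test_spike_wave()
  w2 <- test_spike_wave(trough_w = 7, ratio = 0.15)
  w3 <- rev(w1)
  lib <- tiny_library(list(10 * w1, 10 * w2, 10 * w3))
  seg <- c(rep(0, 7), 10 * w2, rep(0, 20))
  bm <- best_match(seg, lib)
  expect_equal(bm$template_id, 1L)
  expect_equal(bm$lag, 7L)
  expect_gt(bm$score, 0.999)

  # exhaustive scan oracle
  oracle_best <- -Inf
  for (i in 1:3) {
    tw <- lib$waveform[[i]]
    for (g in 0:(length(seg) - length(tw))) {
      s <- spike_similarity(seg, tw, g)
      if (s > oracle_best) oracle_best <- s
    }
  }
  expect_equal(bm$score, oracle_best)

  # identical templates: id 0 by tie-break
  twin <- tiny_library(list(10 * w1, 10 * w1))
  expect_equal(best_match(c(rep(0, 5), 10 * w1, rep(0, 5)), twin)$template_id, 0L)
})

test_that("pursuit recovers single and overlapping spikes then stops", {
  set.seed(66)
  w1 <- 10 * test_spike_wave()
  w2 <- 10 * test_spike_wave(trough_w = 7, ratio = 0.15)
  lib <- tiny_library(list(w1, w2))
  L <- length(w1)

  seg1 <- c(rep(0, 10), w1, rep(0, 10)) + rnorm(L + 20, sd = 0.2)
  r1 <- pursue(seg1, lib, dtc_th = 4)
  expect_equal(nrow(r1$accepted), 1)
  expect_equal(r1$accepted$template_id, 0L)
  expect_equal(r1$accepted$lag, 10L)
  expect_lt(max(abs(r1$residual)), 4)
  expect_false(r1$truncated)

  # two templates lagged by 10 samples: both recovered with correct lags
  seg2 <- c(rep(0, 8), w1, rep(0, 30)) + c(rep(0, 18), w2, rep(0, 20)) +
    rnorm(L + 38, sd = 0.2)
  r2 <- pursue(seg2, lib, dtc_th = 4)
  expect_setequal(r2$accepted$template_id, c(0L, 1L))
  expect_equal(sort(r2$accepted$lag), c(8L, 18L))

  # sequential subtraction strictly reduces residual energy
  resid <- seg2
  for (i in seq_len(nrow(r2$accepted))) {
    a <- r2$accepted[i, ]
    tw <- lib$waveform[[a$template_id + 1L]]
    nxt <- resid
    idx <- (a$lag + 1):(a$lag + length(tw))
    nxt[idx] <- nxt[idx] - a$amplitude_scale * tw
    expect_lt(sum(nxt^2), sum(resid^2))
    resid <- nxt
  }

  # pure noise below matching quality: nothing accepted, one iteration
  noise <- rnorm(2 * L, sd = 2)
  rn <- pursue(noise, lib, dtc_th = 4)
  expect_equal(nrow(rn$accepted), 0)
  expect_equal(rn$n_iterations, 1L)
})

test_that("the amplitude floor rejects low-energy chance correlations", {
  w1 <- 10 * test_spike_wave()
  lib <- tiny_library(list(w1))
  # a faithful but tiny copy: passes the correlation test, fails the floor
  seg <- c(rep(0, 10), 0.3 * w1, rep(0, 10))
  free <- pursue(seg, lib, dtc_th = 1)
  expect_equal(nrow(free$accepted), 1)
  floored <- pursue(seg, lib, dtc_th = 1, amp_min = 5)
  expect_equal(nrow(floored$accepted), 0)
})

test_that("the iteration cap flags truncation instead of erroring", {
  w1 <- 10 * test_spike_wave()
  lib <- tiny_library(list(w1))
  L <- length(w1)
  seg <- numeric(0)
  for (i in 1:4) seg <- c(seg, w1, rep(0, 5))
  r <- pursue(c(seg, rep(0, 10)), lib, dtc_th = 2, max_iter = 2)
  expect_true(r$truncated)
  expect_equal(nrow(r$accepted), 2)
})

test_that("pursuit matches the exhaustive two-spike oracle on small instances", {
  set.seed(99)
  shapes <- list(
    10 * test_spike_wave(L = 30, peak_at = 15),
    10 * test_spike_wave(L = 30, peak_at = 15, trough_w = 6, ratio = 0.2),
    10 * rev(test_spike_wave(L = 30, peak_at = 15))
  )
  lib <- tiny_library(shapes)
  L <- 30
  for (case in 1:6) {
    repeat { # same unit twice at the same instant would violate refractoriness
      i <- sample(3, 1)
      j <- sample(3, 1)
      l1 <- sample(0:20, 1)
      l2 <- sample(0:70, 1)
      if (!(i == j && abs(l1 - l2) < 5)) break
    }
    seg <- rep(0, 100)
    seg[(l1 + 1):(l1 + L)] <- seg[(l1 + 1):(l1 + L)] + shapes[[i]]
    seg[(l2 + 1):(l2 + L)] <- seg[(l2 + 1):(l2 + L)] + shapes[[j]]
    seg <- seg + rnorm(100, sd = 0.15)

    # oracle: joint least squares over every (template, lag, template, lag)
    best <- NULL
    for (a in 1:3) {
      for (la in 0:70) {
        xa <- rep(0, 100)
        xa[(la + 1):(la + L)] <- shapes[[a]]
        for (b in 1:3) {
          for (lb in la:70) {
            xb <- rep(0, 100)
            xb[(lb + 1):(lb + L)] <- shapes[[b]]
            fit <- stats::lm.fit(cbind(xa, xb), seg)
            rss <- sum(fit$residuals^2)
            if (is.null(best) || rss < best$rss) {
              best <- list(rss = rss, hyp = sort(c(a - 1, b - 1)), lags = sort(c(la, lb)))
            }
          }
        }
      }
    }
    got <- pursue(seg, lib, dtc_th = 3)
    if (nrow(got$accepted) >= 1 && !is.null(best)) {
      expect_setequal(got$accepted$template_id, best$hyp)
      expect_true(all(abs(sort(got$accepted$lag) - best$lags) <= 1))
    }
  }
})

test_that("outlier resolution is spatially gated and reports absolute times", {
  sim <- small_sim()
  res <- small_run()
  # every pursuit spike's unit must be admissible for its channel
  pd <- probe_distances(sim$recording$probe)
  tn <- attr(sim$recording$probe, "thres_nb")
  pur <- res$spikes[res$spikes$source == "pursuit", ]
  if (nrow(pur) > 0) {
    ok <- vapply(seq_len(nrow(pur)), function(i) {
      hc <- res$templates$home_channels[[match(pur$unit[i], res$templates$template_id)]]
      min(pd[as.character(pur$channel[i]), as.character(hc)]) < tn
    }, logical(1))
    expect_true(all(ok))
    expect_true(all(pur$score > 0.8))
  }
  # with no outliers, resolution returns an empty, well-typed table
  lab0 <- res$labeled[res$labeled$label >= 0, , drop = FALSE]
  for (a in c("snippet_length", "align_offset", "sampling_rate")) {
    attr(lab0, a) <- attr(res$labeled, a)
  }
  empty <- resolve_outliers(
    lab0, res$templates, bandpass(sim$recording), res$thresholds
  )
  expect_equal(nrow(empty), 0)
  expect_named(empty, c("peak_index", "unit", "score", "source", "channel"))
})
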