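test_that("density clustering resolves the canonical geometries", {
  set.seed(1)
  run <- function(x) hdbscan(x, min_cluster_size = 10, min_samples = 5)

  one <- matrix(rnorm(400), 200, 2)
  expect_equal(run(one)$n_clusters, 1)

  two <- rbind(
    matrix(rnorm(200, sd = 1), 100, 2),
    cbind(rnorm(100, 10), rnorm(100))
  )
  r2 <- run(two)
  expect_equal(r2$n_clusters, 2)
  expect_lte(mean(r2$labels == -1), 0.05)
  # the two halves carry distinct labels
  expect_equal(length(unique(r2$labels[1:100][r2$labels[1:100] >= 0])), 1)
  expect_false(unique(r2$labels[1:100][r2$labels[1:100] >= 0]) ==
    unique(r2$labels[101:200][r2$labels[101:200] >= 0]))

  # five points far from both blobs are marked noise
  far <- matrix(runif(10, 40, 60), 5, 2)
  r3 <- run(rbind(two, far))
  expect_equal(r3$labels[201:205], rep(-1L, 5))
  expect_equal(r3$n_clusters, 2)

  # 5x density contrast must not fool the hierarchy
  vd <- rbind(
    matrix(rnorm(300, sd = 1), 150, 2),
    cbind(rnorm(150, 8, 0.2), rnorm(150, 0, 0.2))
  )
  expect_equal(run(vd)$n_clusters, 2)
})

test_that("clustering output obeys its structural invariants", {
  set.seed(2)
  x <- rbind(matrix(rnorm(240), 120, 2), cbind(rnorm(80, 7), rnorm(80)))
  r <- hdbscan(x, 10, 5)
  expect_length(r$labels, 200)
  labs <- setdiff(sort(unique(r$labels)), -1L)
  expect_identical(labs, seq_along(labs) - 1L) # contiguous 0..k-1
  expect_true(all(table(r$labels[r$labels >= 0]) >= 10))
  expect_identical(r$labels, hdbscan(x, 10, 5)$labels) # deterministic

  # degenerate inputs
  expect_equal(hdbscan(matrix(rnorm(10), 5, 2), 10, 5)$labels, rep(-1L, 5))
  expect_equal(hdbscan(matrix(1, 30, 2), 10, 5)$labels, rep(0L, 30))
})

test_that("clustering agrees with the reference implementation on shared data", {
  # scikit-learn's HDBSCAN (same parameters, allow_single_cluster) is run on
  # identical input as an independent oracle
  set.seed(42)
  cases <- list(
    two_blobs = rbind(matrix(rnorm(200), 100, 2), cbind(rnorm(100, 10), rnorm(100))),
    var_density = rbind(
      matrix(rnorm(300), 150, 2),
      cbind(rnorm(150, 8, 0.2), rnorm(150, 0, 0.2))
    )
  )
  dir <- withr::local_tempdir()
  for (nm in names(cases)) {
    utils::write.csv(cases[[nm]], file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  script <- file.path(dir, "oracle.py")
  writeLines(c(
    "import sys, numpy as np",
    "from sklearn.cluster import HDBSCAN",
    "for nm in sys.argv[1:]:",
    "    X = np.loadtxt(nm + '.csv', delimiter=',', skiprows=1)",
    "    lab = HDBSCAN(min_cluster_size=10, min_samples=5,",
    "                  allow_single_cluster=True, copy=True).fit(X).labels_",
    "    np.savetxt(nm + '_labels.txt', lab, fmt='%d')"
  ), script)
  status <- withr::with_dir(dir, system2("python", c("oracle.py", names(cases)),
    stdout = TRUE, stderr = TRUE
  ))
  for (nm in names(cases)) {
    ref <- scan(file.path(dir, paste0(nm, "_labels.txt")), quiet = TRUE)
    got <- hdbscan(cases[[nm]], 10, 5)$labels
    agree <- mclust::adjustedRandIndex(got, ref)
    expect_gte(agree, 0.99)
  }
})

test_that("feature spaces capture group variance with two components", {
  w <- test_spike_wave()
  same <- make_snippets(rep(0L, 6), seq(100, 600, 100), rep(list(w), 6))
  fs <- fit_features(same)
  expect_equal(ncol(fs$projected), 2)
  expect_lt(max(stats::dist(fs$projected)), 1e-8) # identical snippets coincide

  two_shapes <- make_snippets(
    rep(0L, 8), seq(100, 800, 100),
    c(rep(list(w), 4), rep(list(rev(w)), 4))
  )
  f2 <- fit_features(two_shapes)
  pts <- unique(round(f2$projected, 6))
  expect_equal(nrow(pts), 2) # exactly two points in the plane

  # eigen-decomposition oracle for the variance ratios
  set.seed(8)
  wf <- lapply(1:30, function(i) rnorm(40))
  g <- make_snippets(rep(0L, 30), seq_len(30) * 100, wf, L = 40, align_offset = 20)
  f3 <- fit_features(g)
  ev <- eigen(stats::cov(do.call(rbind, wf)))$values
  expect_equal(f3$explained_variance_ratio, ev[1:2] / sum(ev), tolerance = 1e-8)
  expect_true(all(diff(f3$explained_variance_ratio) <= 0))
  # orthonormal basis
  expect_equal(crossprod(f3$components), diag(2), ignore_attr = TRUE)
})

test_that("per-group clustering labels snippets and flags degenerate groups", {
  w1 <- test_spike_wave()
  w2 <- test_spike_wave(trough_w = 6, ratio = 0.2)
  set.seed(31)
  noisy <- function(w, n) lapply(seq_len(n), function(i) w * 10 + rnorm(length(w), sd = 0.3))
  big <- make_snippets(
    rep(0L, 60), seq_len(60) * 100,
    c(noisy(w1, 30), noisy(w2, 30))
  )
  tiny <- make_snippets(rep(3L, 4), seq_len(4) * 100, noisy(w1, 4))
  groups <- list("0" = big, "3" = tiny)
  lab <- cluster_all(groups)
  g0 <- lab[lab$channel == 0, ]
  expect_equal(length(setdiff(unique(g0$label), -1L)), 2)
  expect_true(all(lab$label[lab$channel == 3] == -1L)) # below min_cluster_size
  expect_true(all(is.na(lab$cluster_key[lab$label == -1L])))
  expect_true(all(!is.na(lab$cluster_key[lab$label >= 0])))
})

test_that("two-spike collision snippets land in the outlier label", {
  # a group holding one unit's spikes plus overlapping-event mixtures with a
  # neighboring unit (collision lag under half a spike width): the mixtures
  # scatter far outside the unit's cluster in feature space and must be
  # marked noise, so that pursuit can recover them later
  w1 <- test_spike_wave()
  w2 <- test_spike_wave(trough_w = 6, ratio = 0.2)
  set.seed(17)
  noisy <- function(w, n) lapply(seq_len(n), function(i) w * 10 + rnorm(length(w), sd = 0.3))
  lagged_mix <- function(lag) {
    m <- 10 * w1 + c(rep(0, lag), 8 * w2[1:(length(w2) - lag)])
    m + rnorm(length(m), sd = 0.3)
  }
  n_coll <- 8 # below min_cluster_size so mixtures cannot form their own cluster
  coll <- lapply(sample(3:12, n_coll, replace = TRUE), lagged_mix)
  g <- make_snippets(
    rep(0L, 40 + n_coll), seq_len(40 + n_coll) * 100,
    c(noisy(w1, 40), coll)
  )
  lab <- cluster_all(list("0" = g))
  # the unit's own spikes mostly stay clustered (boundary points may be
  # deferred to pursuit)
  expect_gte(mean(lab$label[1:40] >= 0), 0.7)
  coll_labels <- lab$label[41:(40 + n_coll)]
  expect_gte(mean(coll_labels == -1L), 0.8)
})

test_that("group labelings are independent of group order", {
  w1 <- test_spike_wave()
  set.seed(23)
  noisy <- function(w, n) lapply(seq_len(n), function(i) w * 10 + rnorm(length(w), sd = 0.3))
  ga <- make_snippets(rep(0L, 25), seq_len(25) * 100, noisy(w1, 25))
  gb <- make_snippets(rep(1L, 25), seq_len(25) * 100, noisy(rev(w1), 25))
  ab <- cluster_all(list("0" = ga, "1" = gb))
  ba <- cluster_all(list("1" = gb, "0" = ga))
  for (ch in c(0L, 1L)) {
    expect_identical(
      ab$label[ab$channel == ch],
      ba$label[ba$channel == ch]
    )
  }
})
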