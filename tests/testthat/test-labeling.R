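movie_like_periods <- function(n_bins) {
  # helper: whole run is task, for label tests that use raw bin vectors
  c(0, n_bins * 2)
}

test_that("binarization separates clean two-level traces", {
  tr <- response_trace(rep(c(0, 1), each = 400), run_id = 1)
  ps <- binarize_trace(tr)[[1]]
  expect_identical(ps$presence, rep(c(FALSE, TRUE), each = 400))

  # pooled clustering: an untouched run yields zero presence samples
  lo <- response_trace(rnorm(500, 0, 0.01), run_id = 1)
  hi <- response_trace(c(rnorm(250, 0, 0.01), rnorm(250, 1, 0.01)), run_id = 2)
  ps2 <- binarize_trace(list(lo, hi))
  expect_identical(sum(ps2[[1]]$presence), 0L)
  expect_gt(sum(ps2[[2]]$presence), 200)

  expect_error(binarize_trace(response_trace(rep(1, 100))),
               class = "humordec_degenerate_trace")
})

test_that("binarization centroids equal the exhaustive-split optimum", {
  set.seed(31)
  for (i in 1:30) {
    n <- sample(5:50, 1)
    x <- rnorm(n, sample(c(0, 3), n, replace = TRUE))
    got <- attr(binarize_trace(response_trace(x, sample_rate = 1)),
                "centroids")
    ref <- oracle_kmeans2(x)
    expect_lt(abs(kmeans2_objective(x, got) - attr(ref, "sse")), 1e-8)
    if (attr(ref, "gap") > 1e-8) {
      expect_equal(unname(got), unname(ref), tolerance = 1e-9,
                   ignore_attr = TRUE)
    }
  }
})

test_that("bin sorting uses half-open 2 s bins with any-sample rule", {
  # 100 Hz: 200 samples per bin; one presence sample at t = 6.01 s
  p <- rep(FALSE, 2000)
  p[602] <- TRUE # sample 602 is t = 6.01 s
  bs <- bin_presence(presence_series(p, sample_rate = 100, run_id = 1))
  expect_identical(which(bs$manipulated) - 1L, 3L)

  # boundary sample t = 4.00 s belongs to bin 2 (half-open convention)
  p2 <- rep(FALSE, 1200)
  p2[401] <- TRUE
  bs2 <- bin_presence(presence_series(p2, sample_rate = 100))
  expect_identical(which(bs2$manipulated) - 1L, 2L)

  expect_false(any(bin_presence(presence_series(rep(FALSE, 800),
                                                sample_rate = 100))$manipulated))
})

test_that("onsets are the first bins of maximal manipulated runs", {
  mk <- function(bins, n = 40) {
    m <- rep(FALSE, n)
    m[bins + 1] <- TRUE
    bin_series(m)
  }
  expect_identical(detect_onsets(mk(c(20, 21, 22)), c(0, 80)), 20L)
  expect_identical(detect_onsets(mk(c(20, 24)), c(0, 80)), c(20L, 24L))
  expect_identical(detect_onsets(mk(integer(0)), c(0, 80)), integer(0))
  # onsets outside the task period are dropped
  expect_identical(detect_onsets(mk(c(2, 20)), c(10, 80)), 20L)
})

test_that("lag labels follow the windowed priority rules", {
  tp <- c(0, 100)
  # no onsets: every task bin neutral
  ll <- assign_lag_labels(integer(0), 50, tp)
  expect_true(all(ll$labels == "neutral"))

  # isolated onset: 3 negative, h0, 4 positive labels, rest neutral
  ll <- assign_lag_labels(20, 50, tp)
  expect_identical(ll$labels[18:25],
                   c("h-6", "h-4", "h-2", "h0", "h2", "h4", "h6", "h8"))
  expect_true(all(ll$labels[-(18:25)] == "neutral"))

  # close onsets: positive lags beat negative lags between them, and the
  # second onset keeps its h0
  ll <- assign_lag_labels(c(20, 24), 50, tp)
  expect_identical(ll$labels[22:29],
                   c("h2", "h4", "h6", "h0", "h2", "h4", "h6", "h8"))

  expect_error(assign_lag_labels(60, 50, tp))
})

test_that("rest-period bins are excluded and onsets must be in task", {
  ll <- assign_lag_labels(20, 50, c(10, 90))
  expect_true(all(ll$labels[1:5] == "excluded"))
  expect_true(all(ll$labels[46:50] == "excluded"))
  expect_error(assign_lag_labels(2, 50, c(10, 90)))
})

test_that("hold-continuation bins can be suppressed (literal variant)", {
  tp <- c(0, 100)
  manip <- rep(FALSE, 50)
  manip[21:23] <- TRUE # onset 20 with a 6 s hold
  ll <- assign_lag_labels(20, 50, tp, manipulated = manip,
                          suppress_hold_bins = TRUE)
  expect_identical(ll$labels[21], "h0")
  expect_identical(ll$labels[22:23], c("excluded", "excluded"))
  expect_identical(ll$labels[24:25], c("h6", "h8"))
  # default keeps the positive-lag labels on hold bins
  ll2 <- assign_lag_labels(20, 50, tp)
  expect_identical(ll2$labels[22:23], c("h2", "h4"))
})

test_that("lag labels match the brute-force enumerator on random patterns", {
  set.seed(91)
  for (i in 1:150) {
    n_bins <- sample(20:120, 1)
    tp <- c(0, n_bins * 2)
    onsets <- sort(sample(0:(n_bins - 1), sample(0:6, 1)))
    ll <- assign_lag_labels(onsets, n_bins, tp)
    expect_identical(ll$labels,
                     oracle_lag_labels(onsets, n_bins, 0:(n_bins - 1)))
  }
})

test_that("label counts obey the onset-window identities", {
  set.seed(17)
  for (i in 1:30) {
    n_bins <- 150
    # onsets separated by > 8 s and away from the run edges
    onsets <- cumsum(sample(6:20, 6, replace = TRUE)) + 5
    onsets <- onsets[onsets < n_bins - 5]
    ll <- assign_lag_labels(onsets, n_bins, c(0, n_bins * 2))
    counts <- table(factor(ll$labels,
                           levels = c("h-6", "h-4", "h-2", "h0", "h2")))
    expect_identical(unname(counts[["h0"]]), unname(counts[["h2"]]))
    # pre-onset counts non-increasing in |t|
    expect_true(counts[["h-2"]] >= counts[["h-4"]])
    expect_true(counts[["h-4"]] >= counts[["h-6"]])
    # non-positive lags never fall after their anchoring onset
    for (t in c(-6, -4, -2)) {
      bins <- which(ll$labels == paste0("h", t)) - 1L
      for (b in bins) expect_true(any(onsets >= b))
    }
  }
})

test_that("marker signals center, square, sum and detrend correctly", {
  # constant coordinates give an identically-zero signal
  ms <- marker_signal(matrix(5, 100, 8), sample_rate = 10)
  expect_true(all(abs(ms$values) < 1e-20))

  # a pure linear drift is removed by detrending
  t <- seq_len(200)
  coords <- cbind(0.01 * t, matrix(0, 200, 7))
  ms2 <- marker_signal(coords, sample_rate = 10)
  slope <- coef(lm(ms2$values ~ t))[2]
  expect_lt(abs(slope), 1e-9)

  # injected motion bursts drive downstream onsets at the burst bins
  set.seed(5)
  n <- 6000 # 60 s at 100 Hz
  coords <- matrix(rnorm(n * 8, 0, 0.02), n, 8)
  burst_bins <- c(5L, 20L)
  t_s <- (seq_len(n) - 1) / 100
  for (b in burst_bins) {
    sel <- t_s >= b * 2 & t_s < b * 2 + 1
    coords[sel, ] <- coords[sel, ] + rnorm(sum(sel) * 8, 0, 2)
  }
  ms3 <- marker_signal(coords, sample_rate = 100)
  ps <- binarize_trace(ms3)[[1]]
  onsets <- detect_onsets(bin_presence(ps), c(0, 60))
  expect_identical(onsets, burst_bins)
})

test_that("laughter traces average pointwise across annotators", {
  a <- response_trace(c(0, 1, 1, 0), sample_rate = 1)
  b <- response_trace(c(0, 0, 1, 1), sample_rate = 1)
  expect_identical(laughter_signal(list(a, a))$values, a$values)
  z <- response_trace(rep(0, 4), sample_rate = 1)
  expect_identical(laughter_signal(list(a, z))$values, a$values / 2)
  expect_error(laughter_signal(list(a, response_trace(1:5, sample_rate = 1))))

  # averaging then labelling equals labelling the hand-computed mean trace
  set.seed(8)
  mk_boxcar <- function(shift) {
    v <- rnorm(4000, 0, 0.01)
    v[(1000 + shift):(1500 + shift)] <- v[(1000 + shift):(1500 + shift)] + 1
    response_trace(v, sample_rate = 100)
  }
  tr1 <- mk_boxcar(0)
  tr2 <- mk_boxcar(30)
  avg <- laughter_signal(list(tr1, tr2))
  manual <- response_trace((tr1$values + tr2$values) / 2, sample_rate = 100)
  o1 <- detect_onsets(bin_presence(binarize_trace(avg)[[1]]), c(0, 40))
  o2 <- detect_onsets(bin_presence(binarize_trace(manual)[[1]]), c(0, 40))
  expect_identical(o1, o2)
})
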