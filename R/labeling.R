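#' Binarize continuous response traces by pooled 1-D 2-means clustering
#'
#' All runs' samples are pooled and partitioned into two clusters by exact
#' one-dimensional 2-means (the split minimizing total within-cluster sum of
#' squares over all contiguous splits of the sorted pooled values, which is
#' the global optimum in one dimension).  The cluster with the larger
#' centroid is "presence" of manipulation; samples are assigned to the
#' nearest centroid, with midpoint ties going to presence.
#'
#' Pooling across runs matters: a run in which the device was never touched
#' contributes only low values and therefore yields no presence samples.
#'
#' @param traces A [response_trace()] or a list of them (one per run).
#' @return A list of [presence_series()], one per input trace.  The attribute
#'   `"centroids"` carries the fitted cluster centroids `c(lo, hi)`.
#' @export
binarize_trace <- function(traces) {
  if (inherits(traces, "response_trace")) traces <- list(traces)
  stopifnot(length(traces) >= 1,
            all(vapply(traces, inherits, logical(1), "response_trace")))
  pooled <- unlist(lapply(traces, `[[`, "values"), use.names = FALSE)
  if (length(unique(pooled)) < 2) {
    stop_humordec("humordec_degenerate_trace",
                  "pooled response values have zero variance; cannot binarize")
  }
  centroids <- kmeans2_1d(pooled)
  thr <- mean(centroids)
  out <- lapply(traces, function(tr) {
    presence_series(tr$values >= thr, sample_rate = tr$sample_rate,
                    run_id = tr$run_id, periods = tr$periods)
  })
  attr(out, "centroids") <- centroids
  out
}

# Exact 1-D 2-means via prefix sums over the sorted values: in one dimension
# both clusters are intervals, so scanning the n - 1 contiguous splits finds
# the global within-SSE optimum deterministically.
kmeans2_1d <- function(x) {
  mu <- mean(x)
  xs <- sort(x) - mu # centering guards the prefix sums against cancellation
  n <- length(xs)
  cs <- cumsum(xs)
  css <- cumsum(xs^2)
  k <- seq_len(n - 1)
  sse1 <- css[k] - cs[k]^2 / k
  sse2 <- (css[n] - css[k]) - (cs[n] - cs[k])^2 / (n - k)
  best <- which.min(sse1 + sse2)
  c(lo = cs[best] / best + mu, hi = (cs[n] - cs[best]) / (n - best) + mu)
}

#' Sort per-sample presence into 2 s bins
#'
#' A bin counts as manipulated when at least one presence sample falls in its
#' half-open interval `[2i, 2i + 2)`.  Samples beyond the last complete bin
#' are dropped.
#'
#' @param presence A [presence_series()].
#' @param bin_width Bin width in seconds (fixed at 2).
#' @return A [bin_series()].
#' @export
bin_presence <- function(presence, bin_width = BIN_WIDTH) {
  stopifnot(inherits(presence, "presence_series"))
  n <- length(presence$presence)
  t_s <- (seq_len(n) - 1) / presence$sample_rate
  n_bins <- floor(n / presence$sample_rate / bin_width)
  if (n_bins < 1) stop("trace shorter than one bin")
  bin <- floor(t_s / bin_width)
  keep <- bin < n_bins
  manip <- vapply(split(presence$presence[keep], bin[keep]), any, logical(1))
  # split() orders by bin value; fill bins with no samples (impossible for
  # sample_rate >= 1/bin_width, but keep the bookkeeping exact)
  out <- logical(n_bins)
  out[as.integer(names(manip)) + 1L] <- manip
  bin_series(out, bin_width = bin_width, run_id = presence$run_id,
             periods = presence$periods)
}

#' Detect event onsets from a binned manipulation series
#'
#' An onset is the first bin of each maximal run of consecutive manipulated
#' bins.  A sustained slider hold therefore yields a single onset.  Onsets
#' outside the task period are dropped.
#'
#' @param bins A [bin_series()].
#' @param task_period Numeric `c(start_s, end_s)` of the task (movie) period;
#'   defaults to the task period annotated on `bins`.
#' @return Sorted integer vector of 0-based onset bin indices.
#' @export
detect_onsets <- function(bins, task_period = NULL) {
  stopifnot(inherits(bins, "bin_series"))
  if (is.null(task_period)) task_period <- task_period_of(bins$periods)
  m <- bins$manipulated
  starts <- which(m & !c(FALSE, m[-length(m)])) - 1L # 0-based
  tb <- task_bins_from_period(task_period, length(m), bins$bin_width)
  sort(starts[starts %in% tb])
}

#' Assign lag labels to the 2 s bins of a run
#'
#' Every bin inside the task period is labelled by its lag (in seconds) to
#' the nearest event onset: `h0` for onset bins, `h2` to `h8` for bins up to
#' 8 s after the most recent onset, `h-2` to `h-6` for bins up to 6 s before
#' the next onset, and `neutral` for bins more than 6 s before and more than
#' 8 s after every onset.  Precedence when several rules apply: an onset bin
#' is always `h0`; labels with positive lag take priority over labels with
#' negative lag; negative-lag bins anchor to the nearest upcoming onset.
#' Bins outside the task period are `excluded`.
#'
#' By default bins inside a sustained hold after an onset receive their
#' positive-lag labels like any other post-onset bin.  With
#' `suppress_hold_bins = TRUE` the continuation bins of a hold (manipulated
#' bins that are not themselves onsets) are excluded from labelling instead;
#' `manipulated` must then be supplied.
#'
#' @param onsets Sorted 0-based onset bin indices (see [detect_onsets()]).
#' @param n_bins Number of bins in the run.
#' @param task_period Numeric `c(start_s, end_s)` of the task period.
#' @param manipulated Optional logical vector of per-bin manipulation, only
#'   consulted when `suppress_hold_bins = TRUE`.
#' @param suppress_hold_bins Exclude hold-continuation bins from labelling.
#' @return An object of class `lag_label_series` with fields `labels`
#'   (character, one of `"h-6" ... "h8"`, `"neutral"`, `"excluded"`),
#'   `onset_bins`, `n_bins`, `task_period`.
#' @export
assign_lag_labels <- function(onsets, n_bins, task_period,
                              manipulated = NULL,
                              suppress_hold_bins = FALSE) {
  onsets <- sort(as.integer(onsets))
  stopifnot(n_bins >= 1)
  if (length(onsets) && (min(onsets) < 0 || max(onsets) >= n_bins)) {
    stop("onset bin outside [0, n_bins)")
  }
  tb <- task_bins_from_period(task_period, n_bins)
  if (length(onsets) && !all(onsets %in% tb)) {
    stop("onsets must lie inside the task period")
  }
  labels <- rep("excluded", n_bins)
  labels[tb + 1L] <- "neutral"

  in_task <- function(b) b %in% tb
  assignable <- function(b) in_task(b) & labels[b + 1L] == "neutral"

  # onset bins first: every onset bin is h0
  labels[onsets + 1L] <- "h0"
  # positive lags, nearest past onset wins (ascending offset)
  for (k in 1:4) {
    b <- onsets + k
    b <- b[b < n_bins]
    b <- b[assignable(b)]
    labels[b + 1L] <- paste0("h", 2L * k)
  }
  # negative lags, nearest upcoming onset wins; positive labels already
  # placed take priority by construction
  for (k in 1:3) {
    b <- onsets - k
    b <- b[b >= 0]
    b <- b[assignable(b)]
    labels[b + 1L] <- paste0("h", -2L * k)
  }

  if (suppress_hold_bins) {
    if (is.null(manipulated)) {
      stop("suppress_hold_bins = TRUE requires `manipulated`")
    }
    stopifnot(length(manipulated) == n_bins)
    hold <- which(manipulated) - 1L
    hold <- setdiff(hold, onsets)
    hold <- hold[hold %in% tb]
    labels[hold + 1L] <- "excluded"
  }

  structure(list(labels = labels, onset_bins = onsets, n_bins = n_bins,
                 task_period = task_period),
            class = "lag_label_series")
}

#' @export
print.lag_label_series <- function(x, ...) {
  cat(sprintf("<lag_label_series> %d bins, %d onsets\n",
              x$n_bins, length(x$onset_bins)))
  print(table(x$labels))
  invisible(x)
}

#' Label one run's trace end to end
#'
#' Convenience chain [bin_presence()] -> [detect_onsets()] ->
#' [assign_lag_labels()] for one [presence_series()].
#'
#' @param presence A [presence_series()].
#' @param task_period Numeric `c(start_s, end_s)`; defaults to the annotated
#'   task period.
#' @param ... Passed to [assign_lag_labels()].
#' @return A `lag_label_series`.
#' @export
label_presence <- function(presence, task_period = NULL, ...) {
  bins <- bin_presence(presence)
  if (is.null(task_period)) task_period <- task_period_of(bins$periods)
  onsets <- detect_onsets(bins, task_period)
  assign_lag_labels(onsets, length(bins$manipulated), task_period,
                    manipulated = bins$manipulated, ...)
}

#' Derive a one-dimensional motion signal from facial-marker coordinates
#'
#' Each marker coordinate is centered on its within-run mean, the squared
#' centered coordinates are summed across markers and axes at each time
#' point, and the resulting 1-D signal is linearly detrended within the run.
#' The output feeds the standard labelling chain ([binarize_trace()] etc.).
#'
#' @param coords Numeric matrix, time points x coordinates (e.g. 4 markers
#'   x 2 axes = 8 columns).
#' @param sample_rate Sampling rate of the marker recording in Hz.
#' @param run_id Run identifier.
#' @param periods Period annotations for the run.
#' @return A [response_trace()].
#' @export
marker_signal <- function(coords, sample_rate = 60, run_id = NA,
                          periods = NULL) {
  coords <- as.matrix(coords)
  stopifnot(is.numeric(coords), nrow(coords) > 1)
  centered <- sweep(coords, 2, colMeans(coords))
  s <- rowSums(centered^2)
  t_s <- (seq_along(s) - 1) / sample_rate
  fit <- stats::lm.fit(cbind(1, t_s), s)
  response_trace(fit$residuals, sample_rate = sample_rate, run_id = run_id,
                 periods = periods)
}

#' Average laughter-annotation traces across annotators
#'
#' @param annotator_traces List of [response_trace()] objects of identical
#'   length and sampling rate, one per annotator.
#' @return A [response_trace()] containing the pointwise mean.
#' @export
laughter_signal <- function(annotator_traces) {
  stopifnot(length(annotator_traces) >= 1,
            all(vapply(annotator_traces, inherits, logical(1), "response_trace")))
  lens <- vapply(annotator_traces, function(tr) length(tr$values), integer(1))
  rates <- vapply(annotator_traces, `[[`, numeric(1), "sample_rate")
  if (length(unique(lens)) != 1 || length(unique(rates)) != 1) {
    stop("annotator traces must share length and sample rate")
  }
  m <- rowMeans(do.call(cbind, lapply(annotator_traces, `[[`, "values")))
  tmpl <- annotator_traces[[1]]
  response_trace(m, sample_rate = tmpl$sample_rate, run_id = tmpl$run_id,
                 periods = tmpl$periods)
}
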