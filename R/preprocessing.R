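#' One run's voxel x volume time series
#'
#' @param data Numeric matrix, voxels x volumes, arbitrary units.
#' @param tr Repetition time in seconds.
#' @param run_id Run identifier.
#' @param periods Period annotations (data frame with `name`, `start_s`,
#'   `end_s`, `is_task`); intervals are half-open and must tile the run.
#' @param discard_count Number of scanner volumes removed at the start of
#'   the run before `data` begins (bookkeeping only).
#' @return An object of class `run_time_series`.
#' @export
run_time_series <- function(data, tr, run_id = NA, periods = NULL,
                            discard_count = 0L) {
  data <- as.matrix(data)
  stopifnot(is.numeric(data), ncol(data) > 0, nrow(data) > 0, tr > 0,
            discard_count >= 0)
  if (!is.null(periods)) {
    stopifnot(is.data.frame(periods))
    o <- order(periods$start_s)
    if (!isTRUE(all.equal(periods$end_s[o][-nrow(periods)],
                          periods$start_s[o][-1])) ||
        !isTRUE(all.equal(max(periods$end_s), ncol(data) * tr)) ||
        !isTRUE(all.equal(min(periods$start_s), 0))) {
      stop("periods must tile [0, n_volumes * tr)")
    }
  }
  structure(list(data = data, tr = tr, run_id = run_id, periods = periods,
                 discard_count = as.integer(discard_count)),
            class = "run_time_series")
}

#' @export
print.run_time_series <- function(x, ...) {
  cat(sprintf("<run_time_series> run %s: %d voxels x %d volumes, TR %g s\n",
              format(x$run_id), nrow(x$data), ncol(x$data), x$tr))
  invisible(x)
}

#' Region-of-interest voxel mask
#'
#' @param roi_name ROI name (e.g. `"dlpfc_r"`).
#' @param voxels Integer vector of 1-based voxel row indices into the run
#'   matrix; must be unique.
#' @param hemisphere Optional hemisphere tag (`"l"`, `"r"` or `NA`).
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(roi_name, voxels, hemisphere = NA) {
  voxels <- as.integer(voxels)
  stopifnot(length(voxels) > 0, all(voxels >= 1), !anyDuplicated(voxels))
  structure(list(roi_name = roi_name, voxels = voxels,
                 hemisphere = hemisphere),
            class = "roi_mask")
}

#' Normalize a run to its initial-rest baseline
#'
#' Each voxel's series is divided by (or, optionally, has subtracted) its
#' own mean over the first `baseline_window` seconds of the run, so that
#' amplitudes are expressed relative to the resting baseline and baseline
#' differences across runs are removed.
#'
#' @param run A [run_time_series()].
#' @param baseline_window Baseline window length in seconds (default the
#'   first 30 s of the initial rest period, i.e. 15 volumes at TR = 2 s).
#' @param method `"divide"` (default, percent-of-baseline scale) or
#'   `"subtract"`.
#' @return A [run_time_series()] with normalized data.
#' @export
normalize_to_rest_baseline <- function(run, baseline_window = 30,
                                       method = c("divide", "subtract")) {
  stopifnot(inherits(run, "run_time_series"))
  method <- match.arg(method)
  nb <- floor(baseline_window / run$tr)
  if (nb < 1) stop("baseline window contains no volumes")
  nb <- min(nb, ncol(run$data))
  base <- rowMeans(run$data[, seq_len(nb), drop = FALSE])
  if (method == "divide" && any(base == 0)) {
    stop_humordec("humordec_baseline_error",
                  "zero baseline mean for voxel(s) ",
                  paste(which(base == 0), collapse = ", "))
  }
  out <- run
  out$data <- if (method == "divide") run$data / base else run$data - base
  out
}

#' Map 2 s bins to acquired volumes
#'
#' With TR equal to the bin width the map is the identity on post-discard
#' indices: bin `i` corresponds to volume `i` (0-based), which is scanner
#' volume `i + discard_count`.
#'
#' @param run A [run_time_series()] with `tr` equal to the 2 s bin width.
#' @return A data frame with columns `bin`, `volume` (both 0-based,
#'   post-discard) and `scanner_volume`.
#' @export
align_bins_to_volumes <- function(run) {
  stopifnot(inherits(run, "run_time_series"))
  if (run$tr != BIN_WIDTH) {
    stop("tr (", run$tr, " s) must equal the ", BIN_WIDTH,
         " s bin width; interpolation is not supported")
  }
  n <- ncol(run$data)
  data.frame(bin = 0:(n - 1), volume = 0:(n - 1),
             scanner_volume = run$discard_count + 0:(n - 1))
}

#' Extract labelled ROI samples from a run
#'
#' Builds one feature vector (the masked voxels of the volume acquired in
#' that bin) per bin whose label is not `excluded`.  No hemodynamic shift
#' is applied: the sample for a bin at lag t is the volume acquired t
#' seconds from the report.
#'
#' @param run A (normalized) [run_time_series()].
#' @param mask A [roi_mask()].
#' @param labels A `lag_label_series` aligned to the run's bins.
#' @return An object of class `labeled_sample_set` with fields `x`
#'   (samples x voxels matrix), `labels`, `bins` (0-based), `run_id`,
#'   `roi_name`.
#' @export
extract_labeled_samples <- function(run, mask, labels) {
  stopifnot(inherits(run, "run_time_series"), inherits(mask, "roi_mask"),
            inherits(labels, "lag_label_series"))
  if (max(mask$voxels) > nrow(run$data)) {
    stop("mask indexes voxels beyond the run matrix")
  }
  n_vol <- ncol(run$data)
  if (labels$n_bins > n_vol) {
    stop("label series longer than run (", labels$n_bins, " bins vs ",
         n_vol, " volumes)")
  }
  keep <- which(labels$labels != "excluded") # 1-based bin+1 == volume column
  x <- t(run$data[mask$voxels, keep, drop = FALSE])
  structure(list(x = x, labels = labels$labels[keep], bins = keep - 1L,
                 run_id = run$run_id, roi_name = mask$roi_name),
            class = "labeled_sample_set")
}

#' @export
print.labeled_sample_set <- function(x, ...) {
  cat(sprintf("<labeled_sample_set> run %s, ROI %s: %d samples x %d voxels\n",
              format(x$run_id), x$roi_name, nrow(x$x), ncol(x$x)))
  invisible(x)
}
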