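#' Continuous behavioral response trace
#'
#' A single run's continuous behavioral signal sampled at a fixed rate:
#' a slider report trace, a derived facial-marker motion signal, or an
#' audience-laughter annotation.  Sample `i` (1-based) is taken at time
#' `(i - 1) / sample_rate` seconds from run start.
#'
#' @param values Numeric vector of samples.
#' @param sample_rate Sampling rate in Hz (slider device: 100 Hz).
#' @param run_id Run identifier (any scalar).
#' @param periods Optional data frame of period annotations with columns
#'   `name`, `start_s`, `end_s`, `is_task`; intervals are half-open
#'   `[start_s, end_s)` and should tile the run.
#' @return An object of class `response_trace`.
#' @export
response_trace <- function(values, sample_rate = 100, run_id = NA, periods = NULL) {
  stopifnot(is.numeric(values), length(values) > 0, sample_rate > 0)
  if (!is.null(periods)) {
    stopifnot(is.data.frame(periods),
              all(c("name", "start_s", "end_s", "is_task") %in% names(periods)))
  }
  structure(list(values = as.numeric(values), sample_rate = sample_rate,
                 run_id = run_id, periods = periods),
            class = "response_trace")
}

#' @export
print.response_trace <- function(x, ...) {
  cat(sprintf("<response_trace> run %s: %d samples @ %g Hz (%.1f s)\n",
              format(x$run_id), length(x$values), x$sample_rate,
              length(x$values) / x$sample_rate))
  invisible(x)
}

#' Per-sample manipulation presence
#'
#' Boolean series marking, for every sample of a [response_trace()], whether
#' the device was judged to be manipulated (see [binarize_trace()]).
#'
#' @param presence Logical vector, one element per source sample.
#' @param sample_rate Sampling rate of the source trace in Hz.
#' @param run_id Run identifier.
#' @param periods Period annotations inherited from the source trace.
#' @return An object of class `presence_series`.
#' @export
presence_series <- function(presence, sample_rate = 100, run_id = NA,
                            periods = NULL) {
  stopifnot(is.logical(presence), length(presence) > 0, sample_rate > 0)
  structure(list(presence = presence, sample_rate = sample_rate,
                 run_id = run_id, periods = periods),
            class = "presence_series")
}

#' Per-bin manipulation series on the 2 s grid
#'
#' @param manipulated Logical vector, one element per 2 s bin; bin `i`
#'   (0-based) covers `[2i, 2i + 2)` seconds from run start.
#' @param bin_width Bin width in seconds (fixed at 2).
#' @param run_id Run identifier.
#' @param periods Period annotations inherited from the source trace.
#' @return An object of class `bin_series`.
#' @export
bin_series <- function(manipulated, bin_width = BIN_WIDTH, run_id = NA,
                       periods = NULL) {
  stopifnot(is.logical(manipulated), bin_width == BIN_WIDTH)
  structure(list(manipulated = manipulated, bin_width = bin_width,
                 run_id = run_id, periods = periods),
            class = "bin_series")
}

# Range of 0-based bins wholly inside the task period(s): used by
# detect_onsets() and assign_lag_labels().  `task_period` is c(start_s, end_s).
task_bins_from_period <- function(task_period, n_bins, bin_width = BIN_WIDTH) {
  stopifnot(length(task_period) == 2, task_period[1] < task_period[2])
  first <- ceiling(task_period[1] / bin_width)
  last <- floor(task_period[2] / bin_width) - 1
  first <- max(first, 0L)
  last <- min(last, n_bins - 1L)
  if (last < first) integer(0) else seq.int(first, last)
}

# Extract the task period (start_s, end_s) from a periods data frame.
task_period_of <- function(periods) {
  stopifnot(is.data.frame(periods), any(periods$is_task))
  tp <- periods[periods$is_task, , drop = FALSE]
  c(min(tp$start_s), max(tp$end_s))
}
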