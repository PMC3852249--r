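#' Read and write behavioral trace CSV files
#'
#' Trace files have columns `time_s,value`; the sampling rate is inferred
#' from the time column on read.
#'
#' @param trace A [response_trace()].
#' @param path File path.
#' @param run_id Run identifier to attach on read.
#' @return `write_trace_csv` returns `path` invisibly; `read_trace_csv`
#'   returns a [response_trace()].
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "response_trace"))
  t_s <- (seq_along(trace$values) - 1) / trace$sample_rate
  utils::write.csv(data.frame(time_s = t_s, value = trace$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path, run_id = NA) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_s", "value") %in% names(df)))
  dt <- diff(df$time_s)
  rate <- 1 / stats::median(dt)
  response_trace(df$value, sample_rate = rate, run_id = run_id)
}

#' Write a lag-label series as TSV
#'
#' Columns: `run`, `bin_index` (0-based), `bin_start_s`, `label`.
#'
#' @param labels A `lag_label_series`.
#' @param path File path.
#' @param run_id Run identifier for the `run` column.
#' @return `path`, invisibly.
#' @export
write_label_series <- function(labels, path, run_id = NA) {
  stopifnot(inherits(labels, "lag_label_series"))
  df <- data.frame(run = run_id, bin_index = seq_len(labels$n_bins) - 1L,
                   bin_start_s = (seq_len(labels$n_bins) - 1L) * BIN_WIDTH,
                   label = labels$labels)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Serialize a decoder to JSON and back
#'
#' @param decoder A `linear_decoder`.
#' @param path File path.
#' @return `read_decoder_json` returns a `linear_decoder`.
#' @export
write_decoder_json <- function(decoder, path) {
  stopifnot(inherits(decoder, "linear_decoder"))
  jsonlite::write_json(unclass(decoder), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_decoder_json
#' @export
read_decoder_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$weights <- as.numeric(obj$weights)
  structure(obj, class = "linear_decoder")
}

#' Write per-fold decoding results as TSV
#'
#' @param report An `analysis_report` (or its `folds` data frame).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_decoding_results <- function(report, path) {
  df <- if (inherits(report, "analysis_report")) report$folds else report
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a synthetic study to plain-text files
#'
#' Per run: a gzipped TSV voxel x volume matrix and a trace CSV; per
#' study: ROI masks (`roi_name`, `voxel_index`), ground-truth onsets
#' (`subject`, `run`, `onset_s`) and the configuration as YAML.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  masks <- do.call(rbind, lapply(study$roi_masks, function(m) {
    data.frame(roi_name = m$roi_name, voxel_index = m$voxels)
  }))
  utils::write.table(masks, file.path(dir, "roi_masks.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  truth <- list()
  for (subject in study$subjects) {
    sdir <- file.path(dir, sprintf("sub-%02d", subject$subject_id))
    dir.create(sdir, showWarnings = FALSE)
    for (rn in subject$runs) {
      base <- file.path(sdir, sprintf("run-%02d", rn$run$run_id))
      con <- gzfile(paste0(base, "_bold.tsv.gz"), "w")
      utils::write.table(rn$run$data, con, sep = "\t", row.names = FALSE,
                         col.names = FALSE)
      close(con)
      write_trace_csv(rn$slider, paste0(base, "_slider.csv"))
      if (!is.null(rn$laughter)) {
        write_trace_csv(rn$laughter, paste0(base, "_laughter.csv"))
      }
      if (length(rn$onsets_s)) {
        truth[[length(truth) + 1]] <-
          data.frame(subject = subject$subject_id, run = rn$run$run_id,
                     onset_s = rn$onsets_s)
      }
    }
  }
  if (length(truth)) {
    utils::write.table(do.call(rbind, truth),
                       file.path(dir, "ground_truth.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  cfg <- study$config
  cfg$roi_spec <- as.list(cfg$roi_spec)
  cfg$hrf_params <- unclass(cfg$hrf_params)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a gzipped voxel x volume matrix written by [write_synthetic_study()]
#'
#' @param path Path to a `*_bold.tsv.gz` file.
#' @param tr,run_id,periods,discard_count Passed to [run_time_series()].
#' @return A [run_time_series()].
#' @export
read_run_matrix <- function(path, tr = 2, run_id = NA, periods = NULL,
                            discard_count = 0L) {
  mat <- as.matrix(utils::read.table(gzfile(path), sep = "\t"))
  dimnames(mat) <- NULL
  run_time_series(mat, tr = tr, run_id = run_id, periods = periods,
                  discard_count = discard_count)
}

#' Read a 4-D NIfTI run into a run time series
#'
#' Optional convenience for real data: loads a 4-D image and flattens it
#' to voxels x volumes, keeping only voxels in `mask_indices` if given.
#' Requires the RNifti package.
#'
#' @param path Path to a 4-D NIfTI file.
#' @param mask_indices Optional 1-based linear voxel indices to keep.
#' @param tr Repetition time (read from the header when `NULL`).
#' @param run_id,periods,discard_count Passed to [run_time_series()].
#' @return A [run_time_series()].
#' @export
read_run_nifti <- function(path, mask_indices = NULL, tr = NULL,
                           run_id = NA, periods = NULL, discard_count = 0L) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("read_run_nifti() requires the RNifti package")
  }
  img <- RNifti::readNifti(path)
  d <- dim(img)
  stopifnot(length(d) == 4)
  mat <- matrix(as.numeric(img), prod(d[1:3]), d[4])
  if (!is.null(mask_indices)) mat <- mat[mask_indices, , drop = FALSE]
  if (is.null(tr)) tr <- RNifti::pixdim(img)[4]
  run_time_series(mat, tr = tr, run_id = run_id, periods = periods,
                  discard_count = discard_count)
}
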