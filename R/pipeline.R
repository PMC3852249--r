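#' Configuration for an end-to-end decoding analysis
#'
#' @param study A `synthetic_study` (or `NULL` if `simulate` is given).
#' @param simulate A [synthetic_study_config()] used to generate the study
#'   when `study` is `NULL`.
#' @param source Labelling source: `"report"` (slider), `"marker"`
#'   (facial-marker motion) or `"laughter"`.
#' @param lags Lags (seconds) to decode, subset of -6, -4, -2, 0, 2, 4, 6, 8.
#' @param rois ROI names to decode (default: all ROIs in the study).
#' @param n_ensemble Ensemble size per decoder.
#' @param cost SVM cost parameter.
#' @param q FDR level for the significance gate.
#' @param detect Compute detection-probability curves for FDR-significant
#'   (ROI, lag) cells.
#' @param seed Seed for all decoding randomness (subsampling streams).
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(study = NULL, simulate = NULL,
                            source = c("report", "marker", "laughter"),
                            lags = LAG_SECONDS, rois = NULL,
                            n_ensemble = 500, cost = 1, q = 0.05,
                            detect = TRUE, seed = 1) {
  source <- match.arg(source)
  stopifnot(all(lags %in% LAG_SECONDS), n_ensemble >= 1, cost > 0)
  if (is.null(study) && is.null(simulate)) {
    stop("either `study` or `simulate` must be given")
  }
  structure(list(study = study, simulate = simulate, source = source,
                 lags = as.integer(lags), rois = rois,
                 n_ensemble = n_ensemble, cost = cost, q = q,
                 detect = detect, seed = seed),
            class = "analysis_config")
}

# Behavioral trace of the requested source for one subject's runs.
subject_traces <- function(study, subject, source) {
  lapply(subject$runs, function(rn) {
    switch(source,
      report = rn$slider,
      marker = {
        if (is.null(rn$markers)) {
          stop("marker traces missing from the study; regenerate with ",
               "generate_aux = TRUE")
        }
        marker_signal(rn$markers$coords,
                      sample_rate = rn$markers$sample_rate,
                      run_id = rn$markers$run_id,
                      periods = rn$slider$periods)
      },
      laughter = {
        if (is.null(rn$laughter)) {
          stop("laughter traces missing from the study; regenerate with ",
               "generate_aux = TRUE")
        }
        rn$laughter
      })
  })
}

# Label all runs of one subject: pooled binarization across runs, then the
# per-run bin / onset / lag-label chain.
label_subject <- function(study, subject, source) {
  traces <- subject_traces(study, subject, source)
  presence <- binarize_trace(traces)
  lapply(presence, label_presence)
}

# Normalized labelled sample sets per (run, roi) for one subject.
subject_sample_sets <- function(study, subject, labels, rois) {
  masks <- study$roi_masks[rois]
  lapply(masks, function(mask) {
    lapply(seq_along(subject$runs), function(r) {
      run <- normalize_to_rest_baseline(subject$runs[[r]]$run)
      extract_labeled_samples(run, mask, labels[[r]])
    })
  })
}

#' Run the full decoding analysis
#'
#' Executes labelling (pooled binarization of the chosen behavioral
#' source, onset detection, lag labels), baseline normalization, balanced-
#' ensemble leave-one-run-out decoding for every requested (ROI, lag)
#' pair and subject, group statistics with FDR correction, and - for
#' cells passing the significance gate - volume-by-volume prediction and
#' peri-onset detection-probability curves.
#'
#' @param config An [analysis_config()].
#' @return A list of class `analysis_report` with elements `results`
#'   (subject x ROI x lag data frame of mean CV AUCs), `folds` (per-fold
#'   AUCs), `summary` (group table, see [summarize_decoding()]),
#'   `detection` (detection curves for significant cells, or `NULL`),
#'   `labels` (per subject), `config`, `seed`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  study <- config$study %||% generate_movie_experiment(config$simulate)
  rois <- config$rois %||% names(study$roi_masks)
  stopifnot(all(rois %in% names(study$roi_masks)))

  all_labels <- list()
  rows <- list()
  fold_rows <- list()
  cv_store <- list() # decoders kept for the detection stage
  sample_store <- list()

  for (si in seq_along(study$subjects)) {
    subject <- study$subjects[[si]]
    labels <- label_subject(study, subject, config$source)
    all_labels[[si]] <- labels
    sets_by_roi <- subject_sample_sets(study, subject, labels, rois)
    sample_store[[si]] <- sets_by_roi
    for (roi in rois) {
      for (lag in config$lags) {
        cv <- cross_validate_lag(sets_by_roi[[roi]], lag,
                                 n_ensemble = config$n_ensemble,
                                 cost = config$cost,
                                 seed = derive_seed(config$seed, si,
                                                    match(roi, rois),
                                                    match(lag, config$lags)),
                                 subject = subject$subject_id,
                                 keep_decoders = config$detect)
        cv_store[[paste(si, roi, lag)]] <- cv
        rows[[length(rows) + 1]] <-
          data.frame(subject = subject$subject_id, roi = roi, lag = lag,
                     auc = cv$mean_auc)
        ok <- !is.na(cv$fold_auc)
        fold_rows[[length(fold_rows) + 1]] <-
          data.frame(subject = subject$subject_id, roi = roi, lag = lag,
                     fold = which(ok), run = names(cv$fold_auc)[ok],
                     auc = cv$fold_auc[ok], row.names = NULL)
      }
    }
  }

  results <- do.call(rbind, rows)
  summary <- summarize_decoding(results, q = config$q)

  detection <- NULL
  if (config$detect) {
    sig <- summary[summary$significant, , drop = FALSE]
    curves <- list()
    for (i in seq_len(nrow(sig))) {
      roi <- sig$roi[i]
      lag <- sig$lag[i]
      per_subj <- list()
      for (si in seq_along(study$subjects)) {
        cv <- cv_store[[paste(si, roi, lag)]]
        sets <- sample_store[[si]][[roi]]
        outcomes <- list()
        onsets <- list()
        for (fold in seq_along(sets)) {
          dec <- cv$decoders[[fold]]
          if (is.null(dec)) next
          outcomes[[length(outcomes) + 1]] <- predict_run(dec, sets[[fold]])
          onsets[[length(onsets) + 1]] <- all_labels[[si]][[fold]]$onset_bins
        }
        if (sum(lengths(onsets)) == 0) next
        dc <- detection_probability(outcomes, onsets)
        dc$subject <- study$subjects[[si]]$subject_id
        per_subj[[length(per_subj) + 1]] <- dc
      }
      if (length(per_subj)) {
        dc_all <- do.call(rbind, per_subj)
        agg <- stats::aggregate(probability ~ lag_s, dc_all, mean)
        agg$roi <- roi
        agg$decoder_lag <- lag
        curves[[length(curves) + 1]] <- agg
      }
    }
    if (length(curves)) detection <- do.call(rbind, curves)
  }

  structure(list(results = results, folds = do.call(rbind, fold_rows),
                 summary = summary, detection = detection,
                 labels = all_labels, config = config, seed = config$seed),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  print(x$summary)
  invisible(x)
}

#' Re-run the analysis with an alternative labelling and compare
#'
#' Runs the full decoding once with the original slider-report labels and
#' once with an alternative labelling source (facial-marker motion or
#' laughter annotations), then compares the two AUC grids cell by cell
#' with paired two-sided t-tests (same subjects) and FDR correction.
#'
#' @param config An [analysis_config()] (its `source` is ignored).
#' @param variant `"marker"` or `"laughter"`.
#' @return A list of class `variant_comparison` with `original`,
#'   `variant` (both `analysis_report`s) and `comparison` (per-cell paired
#'   tests with BH-adjusted p values).
#' @export
run_label_variant_comparison <- function(config,
                                         variant = c("marker", "laughter")) {
  variant <- match.arg(variant)
  stopifnot(inherits(config, "analysis_config"))
  cfg_orig <- config
  cfg_orig$source <- "report"
  cfg_var <- config
  cfg_var$source <- variant
  orig <- run_full_analysis(cfg_orig)
  var <- run_full_analysis(cfg_var)

  key <- function(df) paste(df$roi, df$lag)
  cells <- unique(orig$results[, c("roi", "lag")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel_o <- orig$results$roi == cells$roi[i] & orig$results$lag == cells$lag[i]
    sel_v <- var$results$roi == cells$roi[i] & var$results$lag == cells$lag[i]
    a <- orig$results$auc[sel_o][order(orig$results$subject[sel_o])]
    b <- var$results$auc[sel_v][order(var$results$subject[sel_v])]
    tt <- ttest_between(a, b, paired = TRUE)
    data.frame(roi = cells$roi[i], lag = cells$lag[i],
               mean_auc_original = mean(a), mean_auc_variant = mean(b),
               t = tt$t, p = tt$p)
  })
  comparison <- do.call(rbind, rows)
  fdr <- fdr_bh(comparison$p, q = config$q)
  comparison$p_adj <- fdr$adjusted
  comparison$significant <- fdr$rejected
  structure(list(original = orig, variant = var, variant_source = variant,
                 comparison = comparison),
            class = "variant_comparison")
}
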