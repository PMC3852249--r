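#' Balanced training subsets by majority-class subsampling
#'
#' Class imbalance between sparse event labels and the large neutral pool
#' is removed by random subsampling: each subset keeps the minority class
#' in full and draws, without replacement and independently per subset, an
#' equally sized random subsample of the majority class.
#'
#' @param n_pos,n_neg Class sizes (positive = lag-labelled, negative =
#'   neutral).
#' @param n_subsets Number of subsets (ensemble size), default 500.
#' @param seed Seed for the subsampling stream.
#' @return A list of `n_subsets` lists with elements `pos` and `neg`,
#'   1-based indices into the respective class.
#' @export
balanced_subsets <- function(n_pos, n_neg, n_subsets = 500, seed = NULL) {
  if (n_pos < 1 || n_neg < 1) {
    stop_humordec("humordec_empty_class",
                  "both classes must be non-empty (pos = ", n_pos,
                  ", neg = ", n_neg, ")")
  }
  if (!is.null(seed)) set.seed(seed)
  k <- min(n_pos, n_neg)
  lapply(seq_len(n_subsets), function(s) {
    list(pos = if (n_pos > k) sort(sample.int(n_pos, k)) else seq_len(n_pos),
         neg = if (n_neg > k) sort(sample.int(n_neg, k)) else seq_len(n_neg))
  })
}

#' Train a single linear max-margin decoder
#'
#' Fits a hinge-loss, L2-penalized linear classifier (C-SVC with a linear
#' kernel) on the given samples.  Positive decision values
#' (`x %*% weights + bias > 0`) indicate the event (lag-labelled) class.
#'
#' @param x Numeric matrix, samples x features.
#' @param y Class membership: logical or +1/-1, `TRUE`/+1 for the event
#'   class.
#' @param cost Soft-margin cost parameter C.
#' @return A list with `weights` (per-feature), `bias`, and `alpha` (dual
#'   coefficients).
#' @export
train_linear_decoder <- function(x, y, cost = 1) {
  x <- as.matrix(x)
  y <- if (is.logical(y)) ifelse(y, 1, -1) else as.numeric(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(-1, 1)))
  if (!any(y > 0) || !any(y < 0)) {
    stop_humordec("humordec_empty_class", "both classes must be present")
  }
  if (all(apply(x, 2, function(col) length(unique(col)) == 1))) {
    stop_humordec("humordec_degenerate_features",
                  "all samples identical across classes; cannot separate")
  }
  fit <- .svc_linear_fit(x, y, cost)
  list(weights = as.numeric(fit$weights), bias = fit$bias,
       alpha = as.numeric(fit$alpha))
}

#' Train a balanced-subsampling ensemble decoder
#'
#' Trains one linear decoder per balanced subset (see [balanced_subsets()])
#' and averages the weight vectors and biases arithmetically into a single
#' decoder for one (ROI, lag) pair.
#'
#' @param pos_x,neg_x Feature matrices for the event-labelled and neutral
#'   classes (samples x voxels).
#' @param n_ensemble Number of subsets / ensemble members.
#' @param cost Soft-margin cost parameter C.
#' @param seed Seed for the subsampling stream.
#' @param roi_name,lag,train_runs Decoder identity metadata (lag in
#'   seconds; `train_runs` are the run ids the samples came from, used for
#'   the leakage guard in [predict_run()]).
#' @return An object of class `linear_decoder`.
#' @export
train_ensemble_decoder <- function(pos_x, neg_x, n_ensemble = 500, cost = 1,
                                   seed = NULL, roi_name = NA, lag = NA,
                                   train_runs = NULL) {
  pos_x <- as.matrix(pos_x)
  neg_x <- as.matrix(neg_x)
  stopifnot(ncol(pos_x) == ncol(neg_x), n_ensemble >= 1)
  n_pos <- nrow(pos_x)
  n_neg <- nrow(neg_x)
  subsets <- balanced_subsets(n_pos, n_neg, n_ensemble, seed = seed)
  x <- rbind(pos_x, neg_x)
  y <- c(rep(1, n_pos), rep(-1, n_neg))
  idx <- vapply(subsets, function(s) c(s$pos, n_pos + s$neg),
                integer(2 * min(n_pos, n_neg)))
  idx <- matrix(as.integer(idx), ncol = n_ensemble)
  fit <- .svc_ensemble_fit(x, y, idx, cost)
  structure(list(weights = as.numeric(fit$weights), bias = fit$bias,
                 roi_name = roi_name, lag = lag, n_ensemble = n_ensemble,
                 cost = cost, seed = seed, train_runs = train_runs),
            class = "linear_decoder")
}

#' @export
print.linear_decoder <- function(x, ...) {
  cat(sprintf("<linear_decoder> ROI %s, lag %s s: %d voxels, %d-member ensemble\n",
              format(x$roi_name), format(x$lag), length(x$weights),
              x$n_ensemble))
  invisible(x)
}

#' Area under the ROC curve by pair counting
#'
#' `AUC = P(score_pos > score_neg) + 0.5 P(score_pos = score_neg)` over all
#' positive/negative pairs, computed via the rank-sum identity.  Invariant
#' under strictly increasing transforms of the scores.
#'
#' @param scores Numeric decision values.
#' @param labels Class membership: logical or +1/-1, `TRUE`/+1 positive.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- if (is.logical(labels)) labels else labels > 0
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop_humordec("humordec_single_class",
                  "AUC undefined: test set contains a single class")
  }
  r <- rank(scores) # midranks handle ties as half-wins
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Leave-one-run-out cross-validation for one (ROI, lag) pair
#'
#' For every fold, an ensemble decoder is trained on the lag-labelled and
#' neutral samples of all other runs and evaluated by ROC AUC on the
#' held-out run's decision values.  Folds whose test run lacks either
#' class are skipped and recorded.
#'
#' @param sample_sets List of [extract_labeled_samples()] results, one per
#'   run, all from the same ROI.
#' @param lag Lag in seconds (one of -6, -4, -2, 0, 2, 4, 6, 8).
#' @param n_ensemble,cost See [train_ensemble_decoder()].
#' @param seed Base seed; each fold uses `seed + fold`.
#' @param subject Subject identifier carried into the result.
#' @param keep_decoders Keep the per-fold decoders (needed for
#'   volume-by-volume prediction).
#' @return An object of class `decoding_result` with per-fold AUCs, their
#'   mean, skipped folds, and (optionally) per-fold decoders.
#' @export
cross_validate_lag <- function(sample_sets, lag, n_ensemble = 500, cost = 1,
                               seed = 1, subject = NA,
                               keep_decoders = FALSE) {
  stopifnot(length(sample_sets) >= 2)
  lab <- lag_to_label(lag)
  roi <- sample_sets[[1]]$roi_name
  run_ids <- vapply(sample_sets, function(s) as.character(s$run_id),
                    character(1))
  fold_auc <- rep(NA_real_, length(sample_sets))
  names(fold_auc) <- run_ids
  decoders <- vector("list", length(sample_sets))
  names(decoders) <- run_ids
  for (fold in seq_along(sample_sets)) {
    test <- sample_sets[[fold]]
    test_pos <- test$labels == lab
    test_neg <- test$labels == "neutral"
    if (!any(test_pos) || !any(test_neg)) next # skipped fold
    train <- sample_sets[-fold]
    pos_x <- do.call(rbind, lapply(train, function(s) {
      s$x[s$labels == lab, , drop = FALSE]
    }))
    neg_x <- do.call(rbind, lapply(train, function(s) {
      s$x[s$labels == "neutral", , drop = FALSE]
    }))
    if (nrow(pos_x) == 0 || nrow(neg_x) == 0) {
      stop_humordec("humordec_empty_class",
                    "no training samples for label ", lab, " in fold ", fold)
    }
    dec <- train_ensemble_decoder(pos_x, neg_x, n_ensemble = n_ensemble,
                                  cost = cost, seed = seed + fold,
                                  roi_name = roi, lag = lag,
                                  train_runs = run_ids[-fold])
    sel <- test_pos | test_neg
    dv <- as.numeric(test$x[sel, , drop = FALSE] %*% dec$weights + dec$bias)
    fold_auc[fold] <- roc_auc(dv, test_pos[sel])
    if (keep_decoders) decoders[[fold]] <- dec
  }
  if (all(is.na(fold_auc))) {
    stop_humordec("humordec_no_valid_folds",
                  "no fold had both classes for label ", lab)
  }
  structure(list(subject = subject, roi_name = roi, lag = lag,
                 fold_auc = fold_auc, mean_auc = mean(fold_auc, na.rm = TRUE),
                 skipped_runs = run_ids[is.na(fold_auc)],
                 decoders = if (keep_decoders) decoders),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> subject %s, ROI %s, lag %s s: mean AUC %.3f over %d folds\n",
              format(x$subject), x$roi_name, format(x$lag),
              x$mean_auc, sum(!is.na(x$fold_auc))))
  invisible(x)
}

#' Apply a decoder volume by volume to a held-out run
#'
#' Computes the decision value for every sample of the run and thresholds
#' it into a binary outcome.  Refuses to predict a run that contributed to
#' the decoder's training set (leakage guard).
#'
#' @param decoder A [train_ensemble_decoder()] result.
#' @param samples A `labeled_sample_set` for the run (all task bins).
#' @param threshold Decision threshold for the binary outcome (default 0,
#'   the classifier's natural boundary).
#' @return An object of class `outcome_series` with per-bin `decision`
#'   values and logical `outcome`.
#' @export
predict_run <- function(decoder, samples, threshold = 0) {
  stopifnot(inherits(decoder, "linear_decoder"),
            inherits(samples, "labeled_sample_set"))
  if (!is.null(decoder$train_runs) &&
      as.character(samples$run_id) %in% as.character(decoder$train_runs)) {
    stop_humordec("humordec_leakage",
                  "run ", samples$run_id, " was in the decoder's training set")
  }
  dv <- as.numeric(samples$x %*% decoder$weights + decoder$bias)
  structure(list(run_id = samples$run_id, bins = samples$bins,
                 decision = dv, outcome = dv > threshold,
                 roi_name = decoder$roi_name, lag = decoder$lag,
                 threshold = threshold),
            class = "outcome_series")
}

#' Peri-onset detection probability curve
#'
#' For each lag L on the grid, the probability that the decoder outcome is
#' positive in the bin L seconds from an event onset, over all onsets whose
#' offset bin lies inside the run.
#'
#' @param outcomes List of [predict_run()] results, one per run.
#' @param onsets List (parallel to `outcomes`) of 0-based onset bin
#'   indices per run.
#' @param lag_grid Lags in seconds (default -10 to 10, step 2).
#' @return A data frame of class `detection_curve` with columns `lag_s`,
#'   `probability`, `n` (contributing onsets).
#' @export
detection_probability <- function(outcomes, onsets,
                                  lag_grid = seq(-10, 10, by = 2)) {
  stopifnot(length(outcomes) == length(onsets), length(lag_grid) >= 1,
            all(lag_grid %% BIN_WIDTH == 0))
  if (sum(lengths(onsets)) == 0) {
    stop_humordec("humordec_no_onsets", "no onsets supplied")
  }
  rows <- lapply(lag_grid, function(L) {
    off <- L / BIN_WIDTH
    n <- 0L
    hit <- 0L
    for (i in seq_along(outcomes)) {
      oc <- outcomes[[i]]
      for (o in onsets[[i]]) {
        j <- match(o + off, oc$bins)
        if (!is.na(j)) {
          n <- n + 1L
          hit <- hit + as.integer(oc$outcome[j])
        }
      }
    }
    data.frame(lag_s = L, probability = if (n > 0) hit / n else NA_real_,
               n = n)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("detection_curve", class(out))
  out
}
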