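# Independent brute-force oracles used to validate the package's optimized
# implementations.  These deliberately re-derive each quantity from its
# definition (per-bin rule application, exhaustive split search, pair
# counting, step-up scan) rather than sharing code with the package.

# Lag labels by literal per-bin rule application: a bin is h0 if it is an
# onset; otherwise it takes the positive lag to the most recent onset if
# that lag is <= 8 s; otherwise the negative lag to the nearest upcoming
# onset if >= -6 s; otherwise neutral.  Bins outside the task are excluded.
oracle_lag_labels <- function(onsets, n_bins, task_bins) {
  labels <- rep("excluded", n_bins)
  for (b in task_bins) {
    lab <- "neutral"
    if (b %in% onsets) {
      lab <- "h0"
    } else {
      past <- onsets[onsets < b]
      fut <- onsets[onsets > b]
      pos_lag <- if (length(past)) 2 * (b - max(past)) else Inf
      neg_lag <- if (length(fut)) 2 * (min(fut) - b) else Inf
      if (pos_lag <= 8) {
        lab <- paste0("h", pos_lag)
      } else if (neg_lag <= 6) {
        lab <- paste0("h", -neg_lag)
      }
    }
    labels[b + 1] <- lab
  }
  labels
}

# Global-optimum 1-D 2-means by naive evaluation of every contiguous split
# of the sorted values.
oracle_kmeans2 <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  sses <- numeric(n - 1)
  cents <- vector("list", n - 1)
  for (k in 1:(n - 1)) {
    c1 <- xs[1:k]
    c2 <- xs[(k + 1):n]
    sses[k] <- sum((c1 - mean(c1))^2) + sum((c2 - mean(c2))^2)
    cents[[k]] <- c(lo = mean(c1), hi = mean(c2))
  }
  best <- which.min(sses)
  out <- cents[[best]]
  attr(out, "sse") <- sses[best]
  # gap to the second-best distinct split: zero gap means the optimum is
  # attained by several splits and centroid identity is not well defined
  attr(out, "gap") <- if (n > 2) min(sses[-best]) - sses[best] else Inf
  out
}

# k-means objective of a centroid pair under nearest-centroid assignment
kmeans2_objective <- function(x, centroids) {
  sum(pmin((x - centroids[1])^2, (x - centroids[2])^2))
}

# AUC by explicit pair counting.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Benjamini-Hochberg by the step-up definition: reject the smallest
# p-values up to the largest rank i with p_(i) <= i * q / m.
oracle_bh_rejections <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * q / m)
  rejected <- logical(m)
  if (length(k)) rejected[o[seq_len(max(k))]] <- TRUE
  rejected
}

# iid-Gaussian labelled sample sets (one per run) for decoding tests that
# need the data-structure contract without the generator.
make_gaussian_sets <- function(n_runs = 6, n_pos = 3, n_neut = 40, d = 30,
                               shift = 0, roi = "roiA") {
  lapply(seq_len(n_runs), function(r) {
    n <- n_pos + n_neut
    x <- matrix(rnorm(n * d), n)
    x[seq_len(n_pos), ] <- x[seq_len(n_pos), ] + shift
    structure(list(x = x,
                   labels = c(rep("h0", n_pos), rep("neutral", n_neut)),
                   bins = 0:(n - 1), run_id = r, roi_name = roi),
              class = "labeled_sample_set")
  })
}

# Small movie-study configuration used across tests.
small_movie_config <- function(seed, n_subjects = 1, n_runs = 4, ...) {
  synthetic_study_config(
    n_subjects = n_subjects, n_runs = n_runs, seed = seed,
    generate_aux = FALSE,
    roi_spec = data.frame(roi_name = c("roiA", "roiB"),
                          n_voxels = c(60L, 60L),
                          informative = c(TRUE, FALSE)),
    ...)
}

# Labels and per-ROI sample sets for one subject of a study.
study_sample_sets <- function(study, subject_index, rois,
                              source = "report") {
  sub <- study$subjects[[subject_index]]
  labs <- lapply(binarize_trace(lapply(sub$runs, function(rn) {
    switch(source,
           report = rn$slider,
           laughter = rn$laughter)
  })), label_presence)
  sets <- lapply(study$roi_masks[rois], function(mask) {
    lapply(seq_along(sub$runs), function(r) {
      run <- normalize_to_rest_baseline(sub$runs[[r]]$run)
      extract_labeled_samples(run, mask, labs[[r]])
    })
  })
  list(labels = labs, sets = sets)
}
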