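test_that("balanced subsets equalize class counts by subsampling", {
  subs <- balanced_subsets(20, 1000, n_subsets = 50, seed = 1)
  expect_identical(length(subs), 50L)
  for (s in subs) {
    expect_identical(length(s$pos), 20L)
    expect_identical(length(s$neg), 20L)
    expect_identical(s$pos, 1:20) # minority class used in full
    expect_false(anyDuplicated(s$neg) > 0)
  }

  # balanced classes: no subsampling, every subset identical
  subs2 <- balanced_subsets(15, 15, n_subsets = 5, seed = 2)
  for (s in subs2) {
    expect_identical(s$pos, 1:15)
    expect_identical(s$neg, 1:15)
  }

  # the union of 500 subsets covers nearly the whole neutral pool
  subs3 <- balanced_subsets(20, 1000, n_subsets = 500, seed = 3)
  covered <- length(unique(unlist(lapply(subs3, `[[`, "neg"))))
  expect_gt(covered / 1000, 0.99)

  expect_error(balanced_subsets(0, 10), class = "humordec_empty_class")
})

test_that("the linear decoder is a maximum-margin hinge-loss classifier", {
  # two mirrored 1-D points: boundary at the origin
  fit <- train_linear_decoder(matrix(c(1, -1), 2), c(1, -1))
  expect_lt(abs(fit$bias), 1e-6)
  expect_gt(fit$weights, 0)

  # linearly separable data: perfect training AUC
  set.seed(4)
  x <- rbind(matrix(rnorm(40, 5), 20, 2), matrix(rnorm(40, -5), 20, 2))
  y <- rep(c(1, -1), each = 20)
  fit2 <- train_linear_decoder(x, y)
  dv <- x %*% fit2$weights + fit2$bias
  expect_identical(roc_auc(dv, y), 1)

  expect_error(train_linear_decoder(matrix(1, 4, 3), c(1, 1, -1, -1)),
               class = "humordec_degenerate_features")
})

test_that("the decoder solves the same problem as libsvm", {
  skip_if_not_installed("e1071")
  set.seed(21)
  for (i in 1:8) {
    n <- sample(10:40, 1)
    d <- sample(2:20, 1)
    x <- matrix(rnorm(n * d), n)
    y <- sample(c(-1, 1), n, replace = TRUE)
    if (!any(y > 0) || !any(y < 0)) next
    x[y > 0, 1] <- x[y > 0, 1] + 1
    cost <- sample(c(0.5, 1, 2), 1)
    fit <- train_linear_decoder(x, y, cost = cost)
    ref <- e1071::svm(x, factor(y, levels = c(1, -1)), kernel = "linear",
                      cost = cost, scale = FALSE, tolerance = 1e-6)
    w_ref <- drop(t(ref$coefs) %*% ref$SV)
    b_ref <- -ref$rho
    # libsvm orients its decision values by order of label appearance in
    # the data; align the orientation before comparing the solutions
    if (sum(w_ref * fit$weights) < 0) {
      w_ref <- -w_ref
      b_ref <- -b_ref
    }
    expect_equal(fit$weights, unname(w_ref), tolerance = 1e-3)
    expect_equal(fit$bias, b_ref, tolerance = 1e-3)
  }
})

test_that("duplicating every sample at half cost keeps the boundary", {
  set.seed(33)
  x <- matrix(rnorm(30 * 4), 30)
  y <- rep(c(1, -1), 15)
  x[y > 0, ] <- x[y > 0, ] + 0.8
  a <- train_linear_decoder(x, y, cost = 1)
  b <- train_linear_decoder(rbind(x, x), c(y, y), cost = 0.5)
  expect_equal(a$weights, b$weights, tolerance = 1e-4)
  expect_equal(a$bias, b$bias, tolerance = 1e-4)
})

test_that("ensemble decoders average their members deterministically", {
  set.seed(6)
  pos <- matrix(rnorm(30, 1), 10, 3)
  neg <- matrix(rnorm(30, -1), 10, 3)
  # balanced classes: ensemble equals the single decoder
  ens <- train_ensemble_decoder(pos, neg, n_ensemble = 7, seed = 1)
  single <- train_linear_decoder(rbind(pos, neg), rep(c(1, -1), each = 10))
  expect_equal(ens$weights, single$weights, tolerance = 1e-9)
  expect_equal(ens$bias, single$bias, tolerance = 1e-9)

  # identical seed reproduces identical weights bitwise
  neg_big <- matrix(rnorm(300, -1), 100, 3)
  e1 <- train_ensemble_decoder(pos, neg_big, n_ensemble = 20, seed = 9)
  e2 <- train_ensemble_decoder(pos, neg_big, n_ensemble = 20, seed = 9)
  expect_identical(e1$weights, e2$weights)
  expect_identical(e1$bias, e2$bias)
})

test_that("test AUC is stable in the ensemble size", {
  set.seed(44)
  diffs <- sapply(1:5, function(i) {
    pos <- matrix(rnorm(15 * 10, 0.6), 15, 10)
    neg <- matrix(rnorm(120 * 10), 120, 10)
    te_pos <- matrix(rnorm(15 * 10, 0.6), 15, 10)
    te_neg <- matrix(rnorm(60 * 10), 60, 10)
    auc_for <- function(n_ens) {
      dec <- train_ensemble_decoder(pos, neg, n_ensemble = n_ens, seed = i)
      dv <- rbind(te_pos, te_neg) %*% dec$weights + dec$bias
      roc_auc(dv, rep(c(TRUE, FALSE), c(15, 60)))
    }
    abs(auc_for(50) - auc_for(250))
  })
  expect_lt(mean(diffs), 0.03)
})

test_that("AUC equals the pair-counting definition", {
  # worked example: 2 of 4 discordant pairs
  expect_identical(roc_auc(c(0.9, 0.8, 0.4, 0.35),
                           c(TRUE, FALSE, FALSE, TRUE)), 0.5)
  expect_identical(roc_auc(c(3, 2, 1), c(TRUE, TRUE, FALSE)), 1)
  expect_identical(roc_auc(rep(1, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)),
               class = "humordec_single_class")

  set.seed(55)
  for (i in 1:40) {
    n <- sample(4:30, 1)
    s <- sample(round(rnorm(n), 1)) # coarse values force ties
    y <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(y) || all(y)) next
    expect_equal(roc_auc(s, y), oracle_auc(s, y), tolerance = 1e-12)
    # complement identity and monotone invariance (tie-free variant)
    s2 <- rnorm(n)
    expect_equal(roc_auc(s2, y) + roc_auc(-s2, y), 1, tolerance = 1e-12)
    expect_equal(roc_auc(exp(s2), y), roc_auc(s2, y), tolerance = 1e-12)
  }
})

test_that("leave-one-run-out honours fold structure and leakage rules", {
  set.seed(66)
  sets <- make_gaussian_sets(n_runs = 10, shift = 1)
  cv <- cross_validate_lag(sets, 0, n_ensemble = 10, seed = 1,
                           keep_decoders = TRUE)
  expect_identical(length(cv$fold_auc), 10L)
  expect_identical(sum(is.na(cv$fold_auc)), 0L)
  # leakage audit: the test run never appears among the training runs
  for (fold in seq_along(sets)) {
    expect_false(as.character(sets[[fold]]$run_id) %in%
                   cv$decoders[[fold]]$train_runs)
  }
  # planted shift is decodable
  expect_gt(cv$mean_auc, 0.9)

  # folds whose test run lacks positives are skipped and recorded
  sets2 <- sets
  sets2[[3]]$labels[sets2[[3]]$labels == "h0"] <- "neutral"
  cv2 <- cross_validate_lag(sets2, 0, n_ensemble = 5, seed = 1)
  expect_identical(cv2$skipped_runs, "3")
})

test_that("permuted labels decode at chance", {
  set.seed(77)
  aucs <- sapply(1:15, function(i) {
    sets <- make_gaussian_sets(n_runs = 5, n_pos = 4, n_neut = 30, d = 15)
    cross_validate_lag(sets, 0, n_ensemble = 15, seed = i)$mean_auc
  })
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})

test_that("run prediction thresholds decision values and guards leakage", {
  samples <- structure(list(x = matrix(rnorm(20), 5, 4),
                            labels = rep("neutral", 5), bins = 0:4,
                            run_id = "r9", roi_name = "roi"),
                       class = "labeled_sample_set")
  dec <- structure(list(weights = rep(0, 4), bias = 2, roi_name = "roi",
                        lag = 0, n_ensemble = 1, train_runs = c("r1", "r2")),
                   class = "linear_decoder")
  out <- predict_run(dec, samples)
  expect_true(all(out$outcome))
  dec$bias <- -2
  expect_false(any(predict_run(dec, samples)$outcome))

  dec$weights <- rnorm(4)
  out2 <- predict_run(dec, samples, threshold = 0.3)
  manual <- as.numeric(samples$x %*% dec$weights + dec$bias)
  expect_identical(out2$outcome, manual > 0.3)
  expect_equal(out2$decision, manual)

  dec$train_runs <- c("r9", "r2")
  expect_error(predict_run(dec, samples), class = "humordec_leakage")
})

test_that("detection probability counts onset-aligned positives", {
  mk_out <- function(outcome, bins = seq_along(outcome) - 1L) {
    structure(list(run_id = 1, bins = bins, decision = as.numeric(outcome),
                   outcome = outcome), class = "outcome_series")
  }
  all_pos <- detection_probability(list(mk_out(rep(TRUE, 30))), list(c(10, 20)))
  expect_true(all(all_pos$probability == 1))
  all_neg <- detection_probability(list(mk_out(rep(FALSE, 30))), list(c(10, 20)))
  expect_true(all(all_neg$probability == 0))

  # hand-enumerated pattern: positives at bins 9 and 21 only
  oc <- rep(FALSE, 30)
  oc[c(10, 22)] <- TRUE # bins 9 and 21
  dc <- detection_probability(list(mk_out(oc)), list(c(10, 20)),
                              lag_grid = c(-2, 0, 2))
  expect_equal(dc$probability, c(0.5, 0, 0.5))
  expect_identical(dc$n, c(2L, 2L, 2L))

  # onsets whose offset bin falls outside the run are dropped from n
  dc2 <- detection_probability(list(mk_out(oc)), list(c(0, 10)),
                               lag_grid = c(-2))
  expect_identical(dc2$n, 1L)

  expect_error(detection_probability(list(mk_out(oc)), list(integer(0))),
               class = "humordec_no_onsets")
  expect_error(detection_probability(list(mk_out(oc)), list(10),
                                     lag_grid = numeric(0)))
})
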