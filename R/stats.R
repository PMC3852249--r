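#' One-sample t-test of subject AUCs against chance
#'
#' Tests whether the subject-level AUCs for one (ROI, lag) cell are
#' significantly above the chance level of 0.5 (one-sided, since only
#' above-chance decoding is meaningful).
#'
#' @param aucs Numeric vector of per-subject AUCs.
#' @param chance Chance level (default 0.5).
#' @return A list of class `test_result` with `t`, `p`, `df`, `n`, `kind`.
#' @export
ttest_vs_chance <- function(aucs, chance = 0.5) {
  n <- length(aucs)
  stopifnot(n >= 2)
  if (sd(aucs) == 0) {
    stop("AUCs have zero variance; the t statistic is undefined ",
         "(check that folds/subjects are independent)")
  }
  ht <- t.test(aucs, mu = chance, alternative = "greater")
  structure(list(t = unname(ht$statistic), p = ht$p.value,
                 df = unname(ht$parameter), n = n,
                 kind = "one-sample vs chance"),
            class = "test_result")
}

#' Two-sample t-test between groups of AUCs
#'
#' Unpaired comparisons (e.g. movie-viewing vs control experiment, where
#' the subject groups differ) use Welch's two-sided t-test.  Paired
#' comparisons (e.g. original vs alternative labelling of the same
#' subjects) use a paired two-sided t-test and require equal, matched
#' lengths.
#'
#' @param a,b Numeric vectors of per-subject AUCs.
#' @param paired Paired comparison (same subjects in the same order).
#' @return A list of class `test_result`.
#' @export
ttest_between <- function(a, b, paired = FALSE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (paired) {
    if (length(a) != length(b)) {
      stop("paired comparison requires matched subjects (equal lengths)")
    }
    d <- a - b
    if (sd(d) == 0) {
      # degenerate constant shift: t is +/-Inf (or 0 for identical groups)
      return(structure(list(t = ifelse(mean(d) == 0, 0,
                                       sign(mean(d)) * Inf),
                            p = ifelse(mean(d) == 0, 1, 0),
                            df = length(d) - 1, n = length(a),
                            kind = "paired"),
                       class = "test_result"))
    }
    ht <- t.test(a, b, paired = TRUE)
    kind <- "paired"
  } else {
    ht <- t.test(a, b, var.equal = FALSE)
    kind <- "welch"
  }
  structure(list(t = unname(ht$statistic), p = ht$p.value,
                 df = unname(ht$parameter), n = length(a), kind = kind),
            class = "test_result")
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up FDR control over one family of tests (all ROI x lag cells of a
#' comparison).
#'
#' @param pvals Numeric vector of p values in `[0, 1]`.
#' @param q Target FDR level (default 0.05).
#' @return A list with `rejected` (logical), `adjusted` (BH-adjusted p
#'   values) and `q`.
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  stopifnot(length(pvals) >= 1)
  if (any(is.na(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stop("p values must lie in [0, 1]")
  }
  adjusted <- p.adjust(pvals, method = "BH")
  list(rejected = adjusted <= q, adjusted = adjusted, q = q)
}

#' Group-level summary table over decoding results
#'
#' Aggregates subject-level AUCs into a ROI x lag grid with mean, s.e.m.,
#' one-sided t-test against chance, and BH-FDR-corrected significance
#' flags (the FDR family is all cells of the table).
#'
#' @param results Data frame with columns `subject`, `roi`, `lag`, `auc`
#'   (one row per subject x ROI x lag, `auc` the subject's mean CV AUC).
#' @param q FDR level.
#' @param chance Chance AUC.
#' @return A data frame of class `group_stats_table` with columns `roi`,
#'   `lag`, `n`, `mean_auc`, `sem`, `t`, `p`, `p_adj`, `significant`.
#' @export
summarize_decoding <- function(results, q = 0.05, chance = 0.5) {
  stopifnot(is.data.frame(results),
            all(c("subject", "roi", "lag", "auc") %in% names(results)))
  cells <- unique(results[, c("roi", "lag")])
  cells <- cells[order(cells$roi, cells$lag), , drop = FALSE]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- results$roi == cells$roi[i] & results$lag == cells$lag[i]
    aucs <- results$auc[sel]
    if (length(aucs) < 2) {
      stop("need at least 2 subjects per cell (ROI ", cells$roi[i],
           ", lag ", cells$lag[i], ")")
    }
    if (sd(aucs) == 0) {
      # degenerate cell (e.g. perfect decoding in every subject): the t
      # statistic is +/-Inf; the one-sided p collapses accordingly
      m <- mean(aucs)
      tt <- list(t = ifelse(m == chance, 0, sign(m - chance) * Inf),
                 p = ifelse(m == chance, 0.5, ifelse(m > chance, 0, 1)))
    } else {
      tt <- ttest_vs_chance(aucs, chance = chance)
    }
    data.frame(roi = cells$roi[i], lag = cells$lag[i], n = length(aucs),
               mean_auc = mean(aucs), sem = sd(aucs) / sqrt(length(aucs)),
               t = tt$t, p = tt$p)
  })
  out <- do.call(rbind, rows)
  fdr <- fdr_bh(out$p, q = q)
  out$p_adj <- fdr$adjusted
  out$significant <- fdr$rejected
  class(out) <- c("group_stats_table", class(out))
  out
}
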