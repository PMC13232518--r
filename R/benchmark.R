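# CRISPRi benchmarking statistics: precision-recall / AUPRC, percentile
# bootstrap CIs, operating threshold at fixed recall, and the score vs
# effect-size rank correlation.

#' Precision-recall curve and AUPRC
#'
#' The curve is evaluated at every unique score value, taken as thresholds in
#' descending order with predictions `score >= t` at each (so tied scores
#' enter together). The area is the step-wise (average-precision) sum
#' `sum_i (R_i - R_{i-1}) * P_i`, not a trapezoid.
#'
#' @param scores numeric predictions.
#' @param labels 0/1 vector; both classes must be present.
#' @return list with `thresholds`, `precision`, `recall` (descending
#'   thresholds) and `auprc`.
#' @export
pr_curve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("labels contain a single class")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  # collapse ties: keep the last index of each distinct score
  last <- which(s != c(s[-1], NA) | seq_along(s) == length(s))
  tp <- tp[last]; fp <- fp[last]
  n_pos <- sum(labels == 1)
  precision <- tp / (tp + fp)
  recall <- tp / n_pos
  auprc <- sum(diff(c(0, recall)) * precision)
  list(thresholds = s[last], precision = precision, recall = recall,
       auprc = auprc)
}

#' @rdname pr_curve
#' @export
auprc <- function(scores, labels) pr_curve(scores, labels)$auprc

#' Percentile bootstrap confidence interval for AUPRC
#'
#' Resamples the labelled pair list with replacement `n_boot` times and takes
#' empirical `alpha/2` and `1 - alpha/2` quantiles of the replicate AUPRCs
#' (type-7 quantiles). Replicates containing a single class are redrawn and
#' counted. Bit-reproducible for a fixed seed.
#'
#' @param scores,labels as in [pr_curve()].
#' @param n_boot number of bootstrap replicates (default 10000).
#' @param alpha 1 - confidence level.
#' @param seed integer seed.
#' @return list `low`, `high`, `replicates` (numeric vector), `n_redrawn`.
#' @export
bootstrap_auprc_ci <- function(scores, labels, n_boot = 10000L, alpha = 0.05,
                               seed = 1L) {
  stopifnot(length(scores) == length(labels))
  if (length(unique(labels)) < 2) stop("labels contain a single class")
  n <- length(scores)
  .with_seed(seed, {
    reps <- numeric(n_boot)
    n_redrawn <- 0L
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(labels[idx])) == 2) break
        n_redrawn <- n_redrawn + 1L
      }
      reps[b] <- auprc(scores[idx], labels[idx])
    }
    ci <- unname(quantile(reps, c(alpha / 2, 1 - alpha / 2)))
    list(low = ci[1], high = ci[2], replicates = reps, n_redrawn = n_redrawn)
  })
}

#' Operating threshold at a target recall
#'
#' Returns the largest threshold `t` (from the observed score values, or just
#' below the minimum score when needed) such that `recall(score > t) >=
#' target_recall` under strict-greater binarisation, together with the
#' precision at that threshold.
#'
#' @param scores,labels as in [pr_curve()].
#' @param target_recall in (0, 1].
#' @return list `threshold`, `precision`, `recall`.
#' @export
threshold_at_recall <- function(scores, labels, target_recall = 0.70) {
  if (!(target_recall > 0 && target_recall <= 1)) {
    stop("target_recall must be in (0, 1]")
  }
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("labels contain a single class")
  n_pos <- sum(labels == 1)
  cand <- sort(unique(c(scores, min(scores) - 1)), decreasing = TRUE)
  for (t in cand) {
    pred <- scores > t
    rec <- sum(pred & labels == 1) / n_pos
    if (rec >= target_recall) {
      prec <- if (any(pred)) sum(pred & labels == 1) / sum(pred) else NA_real_
      return(list(threshold = t, precision = prec, recall = rec))
    }
  }
  stop("unreachable: recall 1 is always attained below the minimum score")
}

#' Spearman correlation between scores and perturbation effect sizes
#'
#' Rank correlation with average ranks for ties; errors on constant input
#' (undefined correlation).
#'
#' @param scores model scores.
#' @param effects measured effect sizes (percent change in expression).
#' @return Spearman's rho.
#' @export
score_effect_spearman <- function(scores, effects) {
  keep <- is.finite(scores) & is.finite(effects)
  scores <- scores[keep]; effects <- effects[keep]
  if (length(scores) < 3) stop("need at least 3 paired observations")
  if (sd(scores) == 0 || sd(effects) == 0) {
    stop("Spearman correlation undefined for a constant vector")
  }
  cor(scores, effects, method = "spearman")
}

#' Full benchmark of scored E-G pairs against CRISPRi labels
#'
#' @param scores,labels as in [pr_curve()].
#' @param effects optional effect sizes for the score-effect correlation.
#' @param n_boot bootstrap replicates.
#' @param target_recall recall operating point.
#' @param seed bootstrap seed.
#' @return list of class `eg_benchmark`: `auprc`, `ci` (low/high),
#'   `threshold_at_recall`, `precision_at_threshold`, `recall_at_threshold`,
#'   `spearman_rho` (or NA), `n_pos`, `n_neg`, `n_boot`, `seed`.
#' @export
benchmark_predictions <- function(scores, labels, effects = NULL,
                                  n_boot = 10000L, target_recall = 0.70,
                                  seed = 1L) {
  pr <- pr_curve(scores, labels)
  ci <- bootstrap_auprc_ci(scores, labels, n_boot = n_boot, seed = seed)
  thr <- threshold_at_recall(scores, labels, target_recall)
  if (!(ci$low <= pr$auprc && pr$auprc <= ci$high)) {
    warning("point AUPRC outside the bootstrap CI")
  }
  rho <- if (!is.null(effects)) score_effect_spearman(scores, effects) else NA_real_
  structure(list(
    auprc = pr$auprc, ci = c(low = ci$low, high = ci$high),
    threshold_at_recall = thr$threshold,
    precision_at_threshold = thr$precision,
    recall_at_threshold = thr$recall,
    target_recall = target_recall,
    spearman_rho = rho,
    n_pos = sum(labels == 1), n_neg = sum(labels == 0),
    n_boot = n_boot, n_redrawn = ci$n_redrawn, seed = seed
  ), class = "eg_benchmark")
}

#' @export
print.eg_benchmark <- function(x, ...) {
  cat(sprintf("AUPRC %.4f (95%% CI %.4f-%.4f); precision %.4f at recall %.2f (threshold %.4f)\n",
              x$auprc, x$ci["low"], x$ci["high"], x$precision_at_threshold,
              x$recall_at_threshold, x$threshold_at_recall))
  invisible(x)
}
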