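#' Scored predictions container
#'
#' Pairs per-trial target-class probabilities with true labels and the
#' decision threshold used to harden them.
#'
#' @param scores Numeric vector of target-class probabilities in \[0, 1\].
#' @param labels Integer vector of the same length, 0 = non-target,
#'   1 = target.
#' @param threshold Decision cut-off; a trial is called positive when its
#'   score strictly exceeds it. The default 0.5 equals the argmax rule on a
#'   two-class softmax.
#' @return Object of class `scored_predictions`.
#' @export
scored_predictions <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length")
  if (any(is.na(scores)) || any(scores < 0 | scores > 1))
    stop("scores must lie in [0, 1]")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0 or 1")
  structure(list(scores = as.numeric(scores), labels = as.integer(labels),
                 threshold = threshold),
            class = "scored_predictions")
}

#' Confusion counts at the decision threshold
#'
#' @param scored A [scored_predictions()].
#' @return List of class `confusion_counts` with `tp`, `fp`, `tn`, `fn`;
#'   the four counts partition the trials.
#' @export
confusion <- function(scored) {
  stopifnot(inherits(scored, "scored_predictions"))
  if (length(scored$scores) == 0L) stop("no trials to score")
  pred <- scored$scores > scored$threshold
  pos <- scored$labels == 1L
  structure(list(tp = sum(pred & pos), fp = sum(pred & !pos),
                 tn = sum(!pred & !pos), fn = sum(!pred & pos)),
            class = "confusion_counts")
}

#' Threshold metrics from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, true positive rate `TP/(TP+FN)`, false
#' positive rate `FP/(FP+TN)` and F1 `2TP/(2TP+FP+FN)`. A zero denominator
#' yields `NA` (never a silent 0).
#'
#' @param counts A [confusion()] result.
#' @return Named list `acc`, `tpr`, `fpr`, `f1`.
#' @export
basic_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$tp + counts$tn + counts$fp + counts$fn
  if (total == 0L) stop("empty confusion table")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  list(acc = ratio(counts$tp + counts$tn, total),
       tpr = ratio(counts$tp, counts$tp + counts$fn),
       fpr = ratio(counts$fp, counts$fp + counts$tn),
       f1 = ratio(2 * counts$tp, 2 * counts$tp + counts$fp + counts$fn))
}

#' Pairwise AUC
#'
#' The probability that a random target trial scores above a random
#' non-target trial, `AUC = (1 / (P N)) * sum_i sum_j I(p_i > p_j)` over all
#' positive-negative pairs. Under `tie_policy = "strict"` tied pairs
#' contribute 0 (the literal indicator); under `"half"` (the reporting
#' default, equal to the Mann-Whitney statistic) they contribute 1/2.
#' Computed from rank statistics in O(n log n).
#'
#' @param scored A [scored_predictions()].
#' @param tie_policy `"half"` or `"strict"`.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scored, tie_policy = c("half", "strict")) {
  stopifnot(inherits(scored, "scored_predictions"))
  tie_policy <- match.arg(tie_policy)
  pos <- scored$labels == 1L
  P <- sum(pos); N <- sum(!pos)
  if (P == 0L || N == 0L)
    stop("AUC requires at least one trial of each class")
  r <- rank(scored$scores, ties.method = "average")
  u_half <- sum(r[pos]) - P * (P + 1) / 2            # half-credit tied pairs
  if (tie_policy == "half") return(u_half / (P * N))
  # strict: for positive i, #negatives strictly below equals its pooled
  # min-rank minus its min-rank among positives alone
  rmin <- rank(scored$scores, ties.method = "min")
  rmin_pos <- rank(scored$scores[pos], ties.method = "min")
  sum(rmin[pos] - rmin_pos) / (P * N)
}

#' Bundle the full metric suite
#'
#' @param scored A [scored_predictions()].
#' @param tie_policy Tie handling for the AUC term, see [auc()].
#' @return Object of class `metrics_report`: `acc`, `tpr`, `fpr`, `f1`,
#'   `auc`, the confusion `counts`, and the `threshold`/`tie_policy` used.
#' @export
evaluate_scores <- function(scored, tie_policy = "half") {
  counts <- confusion(scored)
  bm <- basic_metrics(counts)
  a <- if (any(scored$labels == 1L) && any(scored$labels == 0L))
    auc(scored, tie_policy) else NA_real_
  structure(c(bm, list(auc = a, counts = counts,
                       threshold = scored$threshold,
                       tie_policy = tie_policy)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Metrics report (threshold ", x$threshold, ", ties '", x$tie_policy,
      "')\n", sep = "")
  cat(sprintf("  ACC %.4f  TPR %s  FPR %s  F1 %s  AUC %s\n",
              x$acc, format(x$tpr, digits = 4), format(x$fpr, digits = 4),
              format(x$f1, digits = 4), format(x$auc, digits = 4)))
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n",
              x$counts$tp, x$counts$fp, x$counts$tn, x$counts$fn))
  invisible(x)
}
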