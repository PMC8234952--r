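#' Confusion-matrix metrics
#'
#' Accuracy, precision, recall and F-score from confusion counts:
#' `accuracy = (TP + TN) / (TP + FP + TN + FN)`,
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`, and the
#' F-score is the harmonic mean `2 * precision * recall /
#' (precision + recall)`. A zero denominator yields a defined 0 with a
#' warning.
#'
#' @param tp,fp,tn,fn Non-negative integer counts (total must be positive).
#' @return A one-row tibble with columns `tp`, `fp`, `tn`, `fn`,
#'   `accuracy`, `precision`, `recall`, `f_score`.
#' @export
#' @examples
#' confusion_metrics(9, 1, 9, 1)
confusion_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(!vapply(counts, is_wholenumber, logical(1))) || any(counts < 0)) {
    stop_invalid("Confusion counts must be non-negative whole numbers.")
  }
  total <- sum(counts)
  if (total == 0) stop_invalid("At least one count must be positive.")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warn(sprintf("%s has a zero denominator; reporting 0.", what))
      0
    } else {
      num / den
    }
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f_score <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = (tp + tn) / total,
    precision = precision,
    recall = recall,
    f_score = f_score
  )
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC: the probability that a randomly chosen
#' positive scores above a randomly chosen negative, with ties counted as
#' one half. Equals the trapezoidal area under the (FPR, TPR) curve traced
#' by sweeping the decision threshold.
#'
#' @param scores Numeric anomaly scores (higher = more anomalous).
#' @param labels Logical (or 0/1) labels; `TRUE` marks a true anomaly. Both
#'   classes must be present.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels)) {
    stop_invalid("`scores` and `labels` must be equal-length and free of NAs.")
  }
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop_invalid("Both classes must be present to compute the AUROC.")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve points
#'
#' True- and false-positive rates at every distinct score threshold
#' (plus the two trivial endpoints), ordered by increasing FPR.
#'
#' @inheritParams auroc
#' @return A tibble with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop_invalid("Both classes must be present to compute a ROC curve.")
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- t(vapply(thr, function(t) {
    pred <- scores >= t
    c(fpr = sum(pred & !labels) / n_neg, tpr = sum(pred & labels) / n_pos)
  }, numeric(2)))
  tibble::tibble(threshold = thr, fpr = pts[, "fpr"], tpr = pts[, "tpr"]) |>
    dplyr::arrange(.data$fpr, .data$tpr)
}

#' Metrics from scores, labels and a threshold
#'
#' Convenience wrapper: thresholds the scores, tabulates the confusion
#' counts and returns [confusion_metrics()] plus the [auroc()].
#'
#' @inheritParams auroc
#' @param threshold Decision threshold; scores strictly above it are
#'   called anomalous.
#' @return One-row tibble of counts, threshold metrics and AUROC.
#' @export
score_metrics <- function(scores, labels, threshold) {
  labels <- as.logical(labels)
  pred <- scores > threshold
  m <- confusion_metrics(
    tp = sum(pred & labels), fp = sum(pred & !labels),
    tn = sum(!pred & !labels), fn = sum(!pred & labels)
  )
  m$auroc <- auroc(scores, labels)
  m
}
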