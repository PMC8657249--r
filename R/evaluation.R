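# Test-set evaluation: confusion matrix at a threshold, the standard metric
# suite (accuracy, sensitivity, specificity, balanced accuracy), and
# rank-statistic ROC/AUC.

#' Confusion counts at a probability threshold
#'
#' A case is called positive when its probability is greater than or equal to
#' the threshold.
#'
#' @param probs positive-class probabilities.
#' @param labels integer 0/1 labels aligned with `probs`.
#' @param threshold decision cutoff (default 0.5).
#' @return named integer vector `c(tp, fp, tn, fn)`.
#' @export
confusion_at_threshold <- function(probs, labels, threshold = 0.5) {
  if (!length(probs)) stop("empty input", call. = FALSE)
  if (length(probs) != length(labels)) stop("probs/labels length mismatch", call. = FALSE)
  pred <- probs >= threshold
  c(tp = sum(pred & labels == 1L),
    fp = sum(pred & labels == 0L),
    tn = sum(!pred & labels == 0L),
    fn = sum(!pred & labels == 1L))
}

#' Metric suite from confusion counts
#'
#' Balanced accuracy is defined as the mean of sensitivity and specificity.
#'
#' @param tp,fp,tn,fn nonnegative counts; either positional or a single named
#'   vector as returned by [confusion_at_threshold()] passed to `tp`.
#' @return list with `accuracy`, `sensitivity`, `specificity`,
#'   `balanced_accuracy`, and the counts.
#' @export
metrics_from_confusion <- function(tp, fp = NULL, tn = NULL, fn = NULL) {
  if (length(tp) == 4L && is.null(fp)) {
    fn <- tp[["fn"]]; tn <- tp[["tn"]]; fp <- tp[["fp"]]; tp <- tp[["tp"]]
  }
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (tp + fn == 0) stop("no positive cases; sensitivity undefined", call. = FALSE)
  if (tn + fp == 0) stop("no negative cases; specificity undefined", call. = FALSE)
  n <- sum(counts)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  list(accuracy = (tp + tn) / n,
       sensitivity = sens,
       specificity = spec,
       balanced_accuracy = (sens + spec) / 2,
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' ROC curve and AUC
#'
#' AUC is computed by the rank statistic (probability that a random positive
#' scores above a random negative, ties counted half), which equals the
#' trapezoidal area under the ROC curve. ROC points run from (0, 0) to
#' (1, 1), stepping at each distinct score.
#'
#' @param probs scores or probabilities.
#' @param labels integer 0/1 labels; both classes must be present.
#' @return list with `auc` and `roc_points` (data.frame `fpr`, `tpr`).
#' @export
roc_auc <- function(probs, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes required for ROC", call. = FALSE)
  r <- rank(probs, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(probs, decreasing = TRUE)
  lab_sorted <- labels[ord]
  p_sorted <- probs[ord]
  # step only after the last of each tied score block
  block_end <- c(p_sorted[-1L] != p_sorted[-length(p_sorted)], TRUE)
  tpr <- cumsum(lab_sorted == 1L)[block_end] / n1
  fpr <- cumsum(lab_sorted == 0L)[block_end] / n0
  roc_points <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  list(auc = auc, roc_points = roc_points)
}

#' Full metrics report for one prediction vector
#'
#' @inheritParams confusion_at_threshold
#' @return list combining [metrics_from_confusion()] and [roc_auc()] output.
#' @export
metrics_report <- function(probs, labels, threshold = 0.5) {
  conf <- confusion_at_threshold(probs, labels, threshold)
  m <- metrics_from_confusion(conf)
  r <- roc_auc(probs, labels)
  c(m, list(auc = r$auc, roc_points = r$roc_points, threshold = threshold))
}
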