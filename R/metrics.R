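# Six-metric evaluation for binary DTI prediction. Threshold metrics follow
# the standard confusion-table definitions; ROCAUC is trapezoidal, PRAUC is
# step-wise average precision (robust on negative-skewed test sets, where it
# is the emphasised metric).

#' Confusion counts at a score threshold
#'
#' Scores equal to the threshold count as positive predictions.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary 0/1 labels.
#' @param threshold Decision threshold (default 0.5).
#' @return Named integer vector `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  pred <- as.integer(scores >= threshold)
  c(TP = sum(pred == 1L & labels == 1),
    TN = sum(pred == 0L & labels == 0),
    FP = sum(pred == 1L & labels == 0),
    FN = sum(pred == 0L & labels == 1))
}

#' Area under the ROC curve (trapezoidal)
#'
#' @param scores,labels As in [confusion_counts()]; both classes must be
#'   present.
#' @return ROCAUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) stop("ROCAUC undefined: test set has a single class")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # walk score thresholds; ties handled by grouping equal scores
  tps <- cumsum(y); fps <- cumsum(1 - y)
  last <- c(diff(s) != 0, TRUE)
  tpr <- c(0, tps[last] / np); fpr <- c(0, fps[last] / nn)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Area under the precision-recall curve
#'
#' Default is step-wise average precision (sum of precision at each recall
#' increment); `method = "trapezoid"` integrates the PR curve instead.
#'
#' @param scores,labels As in [confusion_counts()].
#' @param method `"step"` (average precision, default) or `"trapezoid"`.
#' @return PRAUC in `(0, 1]`.
#' @export
pr_auc <- function(scores, labels, method = c("step", "trapezoid")) {
  method <- match.arg(method)
  np <- sum(labels == 1)
  if (np == 0 || sum(labels == 0) == 0) stop("PRAUC undefined: test set has a single class")
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]; s <- scores[ord]
  tps <- cumsum(y)
  prec <- tps / seq_along(y)
  rec <- tps / np
  last <- c(diff(s) != 0, TRUE)  # evaluate at distinct-score boundaries
  prec <- prec[last]; rec <- rec[last]
  if (method == "step") {
    sum(diff(c(0, rec)) * prec)
  } else {
    sum(diff(c(0, rec)) * (c(1, utils::head(prec, -1)) + prec) / 2)
  }
}

#' Six-metric evaluation of prediction scores
#'
#' Sensitivity SN = TP/(TP+FN), specificity SP = TN/(TN+FP), precision
#' PR = TP/(TP+FP), F1 = 2 PR SN / (PR + SN), plus ROCAUC and PRAUC.
#'
#' @param scores,labels As in [confusion_counts()].
#' @param threshold Decision threshold for SN/SP/PR/F1.
#' @return Named numeric vector `SN`, `SP`, `PR`, `F1`, `ROCAUC`, `PRAUC`.
#' @export
dti_metrics <- function(scores, labels, threshold = 0.5) {
  cc <- confusion_counts(scores, labels, threshold)
  sn <- cc["TP"] / (cc["TP"] + cc["FN"])
  sp <- cc["TN"] / (cc["TN"] + cc["FP"])
  pr <- if (cc["TP"] + cc["FP"] == 0) NA_real_ else cc["TP"] / (cc["TP"] + cc["FP"])
  f1 <- if (is.na(pr) || pr + sn == 0) NA_real_ else 2 * pr * sn / (pr + sn)
  c(SN = unname(sn), SP = unname(sp), PR = unname(pr), F1 = unname(f1),
    ROCAUC = roc_auc(scores, labels), PRAUC = pr_auc(scores, labels))
}
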