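# Confusion-matrix metrics, ROC/AUC, threshold sweeps ----------------------
#
# Class 1 (periodic/exon) is the positive class throughout. Undefined
# ratios (zero denominator) are reported as 0 and flagged rather than NA,
# keeping reports total.

#' Confusion counts between predicted and true classes
#'
#' @param predicted,truth integer vectors with labels in \{1, 2\}; class 1
#'   is positive.
#' @return an object of class `confusion_counts`: list with TP, FP, TN, FN.
#' @export
confusion <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("'predicted' and 'truth' differ in length", call. = FALSE)
  }
  if (!all(c(predicted, truth) %in% c(1L, 2L))) {
    stop("labels must be in {1, 2}", call. = FALSE)
  }
  structure(list(
    TP = sum(predicted == 1L & truth == 1L),
    FP = sum(predicted == 1L & truth == 2L),
    TN = sum(predicted == 2L & truth == 2L),
    FN = sum(predicted == 2L & truth == 1L)),
    class = "confusion_counts")
}

.safe_ratio <- function(num, den) {
  if (den == 0) list(value = 0, flagged = TRUE)
  else list(value = num / den, flagged = FALSE)
}

#' Scalar classification metrics from confusion counts
#'
#' Precision TP/(TP+FP), recall TP/(TP+FN), F1 2TP/(2TP+FP+FN), accuracy
#' (TP+TN)/total and BER (FP+FN)/total (= 1 - accuracy). Zero-denominator
#' ratios are reported as 0 and listed in `flagged`.
#'
#' @param c a `confusion_counts`.
#' @return list with `precision`, `recall`, `f1`, `accuracy`, `ber`,
#'   `flagged` (character vector of undefined metrics).
#' @export
metrics <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  total <- c$TP + c$FP + c$TN + c$FN
  if (total == 0) stop("no evaluated samples", call. = FALSE)
  pr <- .safe_ratio(c$TP, c$TP + c$FP)
  rc <- .safe_ratio(c$TP, c$TP + c$FN)
  f1 <- .safe_ratio(2 * c$TP, 2 * c$TP + c$FP + c$FN)
  flagged <- c(if (pr$flagged) "precision", if (rc$flagged) "recall",
               if (f1$flagged) "f1")
  list(precision = pr$value, recall = rc$value, f1 = f1$value,
       accuracy = (c$TP + c$TN) / total,
       ber = (c$FP + c$FN) / total,
       flagged = flagged %||% character(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' ROC curve and AUC from class-1 scores
#'
#' Thresholds sweep over the unique scores (equal scores collapse to one
#' threshold); the area is computed by the trapezoidal rule over
#' (false-positive rate, true-positive rate) points.
#'
#' @param scores numeric scores for class 1 (higher = more class-1).
#' @param truth integer labels in \{1, 2\}; both classes must be present.
#' @return list with `roc_points` (data.frame fpr, tpr, threshold) and
#'   `auc`.
#' @export
roc_and_auc <- function(scores, truth) {
  if (length(scores) != length(truth)) {
    stop("'scores' and 'truth' differ in length", call. = FALSE)
  }
  pos <- truth == 1L
  if (!any(pos) || all(pos)) {
    stop("both classes must be present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- !duplicated(s, fromLast = TRUE)     # one point per unique score
  tpr <- c(0, tp[last] / sum(pos))
  fpr <- c(0, fp[last] / sum(!pos))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc_points = data.frame(fpr = fpr, tpr = tpr,
                               threshold = c(Inf, s[last])),
       auc = auc)
}

#' Threshold sweep table
#'
#' One row per unique threshold (predict class 1 when score >= threshold):
#' sensitivity is non-increasing and specificity non-decreasing in the
#' threshold.
#'
#' @inheritParams roc_and_auc
#' @return data.frame with threshold, sensitivity, specificity, precision,
#'   recall, accuracy.
#' @export
threshold_sweep <- function(scores, truth) {
  thresholds <- sort(unique(scores))
  rows <- lapply(thresholds, function(th) {
    pred <- ifelse(scores >= th, 1L, 2L)
    cc <- confusion(pred, truth)
    m <- metrics(cc)
    spec <- if ((cc$TN + cc$FP) == 0) 0 else cc$TN / (cc$TN + cc$FP)
    data.frame(threshold = th, sensitivity = m$recall, specificity = spec,
               precision = m$precision, recall = m$recall,
               accuracy = m$accuracy)
  })
  do.call(rbind, rows)
}

#' Full metrics report for a fitted classifier on an evaluation split
#'
#' @param scores matrix of class probabilities (columns class1, class2) or
#'   numeric vector of class-1 scores.
#' @param truth integer labels in \{1, 2\}.
#' @return list with scalar metrics, `auc`, `roc_points`, and the
#'   confusion counts.
#' @export
metrics_report <- function(scores, truth) {
  s1 <- if (is.matrix(scores)) scores[, 1] else scores
  pred <- ifelse(s1 >= 0.5, 1L, 2L)
  cc <- confusion(pred, truth)
  m <- metrics(cc)
  roc <- roc_and_auc(s1, truth)
  c(m, list(auc = roc$auc, roc_points = roc$roc_points, confusion = cc))
}
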