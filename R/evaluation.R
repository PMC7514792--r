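# Confusion-matrix metrics, ROC curve and trapezoidal AUC. The decision
# rule is strict: an image is called positive (adequate quality) when its
# score exceeds the threshold; ties at the threshold count negative.

#' Confusion counts at a threshold
#'
#' @param scores classifier outputs; @param labels binary 0/1 (1 positive);
#' @param th decision threshold (positive iff score > th, strict).
#' @return named integer vector `c(tp, fp, tn, fn)`.
#' @export
confusionCounts <- function(scores, labels, th) {
  if (length(scores) != length(labels)) stop("length mismatch")
  pred <- scores > th
  pos <- labels == 1
  c(tp = sum(pred & pos), fp = sum(pred & !pos),
    tn = sum(!pred & !pos), fn = sum(!pred & pos))
}

#' Classification metrics from confusion counts
#'
#' Sensitivity, specificity, accuracy, positive predictive value and
#' F-score, computed in exact rational arithmetic as fractions; undefined
#' ratios (zero denominators) are returned as NA. Percentage displays use
#' round-half-up to 2 decimals (see [roundHalfUp()]).
#'
#' @param tp,fp,tn,fn nonnegative confusion counts.
#' @return list with `se`, `sp`, `acc`, `ppv`, `f1` (fractions in \[0, 1\])
#'   plus the counts and rounded percentage fields `se_pct`, `sp_pct`,
#'   `acc_pct`, `ppv_pct` and `f1_round` (4 decimals).
#' @export
classificationMetrics <- function(tp, fp, tn, fn) {
  if (any(c(tp, fp, tn, fn) < 0)) stop("counts must be nonnegative")
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  se <- safe(tp, tp + fn)
  sp <- safe(tn, tn + fp)
  acc <- safe(tp + tn, tp + fp + tn + fn)
  ppv <- safe(tp, tp + fp)
  f1 <- if (!is.na(se) && !is.na(ppv) && (se + ppv) > 0)
    2 * se * ppv / (se + ppv) else NA_real_
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       se = se, sp = sp, acc = acc, ppv = ppv, f1 = f1,
       se_pct = roundHalfUp(100 * se), sp_pct = roundHalfUp(100 * sp),
       acc_pct = roundHalfUp(100 * acc), ppv_pct = roundHalfUp(100 * ppv),
       f1_round = roundHalfUp(f1, 4))
}

#' ROC curve and trapezoidal AUC
#'
#' Threshold sweep over the unique scores (strict `>` rule); points are
#' returned in increasing FPR/TPR order including the (0,0) and (1,1)
#' endpoints.
#'
#' @param scores classifier outputs; @param labels binary 0/1.
#' @return list with `points` (data.frame fpr, tpr) and `auc`.
#' @export
rocCurve <- function(scores, labels) {
  if (length(unique(labels)) < 2) stop("labels contain a single class")
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  # descending unique thresholds give nondecreasing (fpr, tpr)
  us <- sort(unique(scores), decreasing = TRUE)
  ord <- order(scores, decreasing = TRUE)
  cp <- cumsum(labels[ord] == 1)
  cn <- cumsum(labels[ord] == 0)
  last <- cumsum(as.vector(table(factor(scores[ord],
                                        levels = us))))
  tpr <- c(0, cp[last] / npos, 1)
  fpr <- c(0, cn[last] / nneg, 1)
  keep <- !duplicated(cbind(fpr, tpr))
  pts <- data.frame(fpr = fpr[keep], tpr = tpr[keep])
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

#' Full evaluation report
#'
#' @param scores classifier outputs; @param labels binary 0/1;
#' @param th decision threshold.
#' @return list with confusion counts, metrics, ROC points, AUC and the
#'   threshold used.
#' @export
evaluateScores <- function(scores, labels, th) {
  cc <- confusionCounts(scores, labels, th)
  roc <- rocCurve(scores, labels)
  c(classificationMetrics(cc["tp"], cc["fp"], cc["tn"], cc["fn"]),
    list(roc_points = roc$points, auc = roc$auc, threshold = th))
}
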