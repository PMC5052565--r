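#' Confusion-matrix performance metrics
#'
#' With coding as the positive class: overall accuracy
#' `ACC = (TP+TN)/n`, sensitivity `Sn = TP/(TP+FN)`, specificity
#' `Sp = TN/(TN+FP)`, positive/negative predictive values
#' `PPV = TP/(TP+FP)`, `NPV = TN/(TN+FN)`, and Matthews correlation
#' coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' A ratio with a zero denominator is reported as `NaN` (with a warning
#' and the `degenerate` flag set) rather than silently imputed.
#'
#' @param predicted,truth Equal-length label vectors
#'   (`"coding"`/`"noncoding"` or 1/0).
#' @return List of class `confusion_metrics`: `TP`, `FP`, `TN`, `FN`,
#'   `ACC`, `Sn`, `Sp`, `PPV`, `NPV`, `MCC`, `degenerate`.
#' @export
confusion_metrics <- function(predicted, truth) {
  p <- as_binary_label(predicted)
  y <- as_binary_label(truth)
  if (length(p) == 0L) stop("empty input")
  if (length(p) != length(y)) stop("predicted and truth lengths differ")
  tp <- sum(p == 1L & y == 1L); fp <- sum(p == 1L & y == 0L)
  tn <- sum(p == 0L & y == 0L); fn <- sum(p == 0L & y == 1L)
  ratio <- function(num, den) if (den == 0) NaN else num / den
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  out <- list(TP = tp, FP = fp, TN = tn, FN = fn,
              ACC = (tp + tn) / length(p),
              Sn = ratio(tp, tp + fn), Sp = ratio(tn, tn + fp),
              PPV = ratio(tp, tp + fp), NPV = ratio(tn, tn + fn),
              MCC = if (mcc_den == 0) NaN else (tp * tn - fp * fn) / mcc_den)
  out$degenerate <- any(is.nan(unlist(out[c("Sn", "Sp", "PPV", "NPV", "MCC")])))
  if (out$degenerate) {
    warning("degenerate confusion table: some metrics are NaN")
  }
  class(out) <- "confusion_metrics"
  out
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("TP=%d FP=%d TN=%d FN=%d\n", x$TP, x$FP, x$TN, x$FN))
  cat(sprintf("ACC=%.4f Sn=%.4f Sp=%.4f PPV=%.4f NPV=%.4f MCC=%.4f\n",
              x$ACC, x$Sn, x$Sp, x$PPV, x$NPV, x$MCC))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Computed as the normalized Mann-Whitney U statistic via midranks, so
#' tied scores earn 0.5 credit; identical to the trapezoidal area under
#' the empirical ROC over all thresholds.
#'
#' @param scores Numeric classifier scores (higher = more coding-like).
#' @param truth Labels (`"coding"`/`"noncoding"` or 1/0); both classes
#'   must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, truth) {
  y <- as_binary_label(truth)
  if (length(scores) != length(y)) stop("scores and truth lengths differ")
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[y == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve points
#'
#' One row per distinct threshold (descending), with the trivial
#' (0, 0) endpoint included.
#'
#' @inheritParams roc_auc
#' @return data.frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, truth) {
  y <- as_binary_label(truth)
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y[ord]
  last <- cumsum(rle(s)$lengths)
  data.frame(threshold = c(Inf, s[last]),
             fpr = c(0, cumsum(yy == 0L)[last] / n_neg),
             tpr = c(0, cumsum(yy == 1L)[last] / n_pos))
}

#' Cutoff with the best overall accuracy
#'
#' Sweeps decision cutoffs at the midpoints between consecutive sorted
#' unique scores (plus the extremes, so all-positive and all-negative
#' calls are reachable) and returns the cutoff maximizing accuracy of
#' the rule "coding iff score >= cutoff"; ties break toward the smallest
#' cutoff. The returned cutoff is snapped to the `grid_step` reporting
#' resolution when doing so does not change the achieved accuracy.
#'
#' @inheritParams roc_auc
#' @param grid_step Reporting resolution for the returned cutoff.
#' @return List with `cutoff` and `accuracy`.
#' @export
best_accuracy_cutoff <- function(scores, truth, grid_step = 1e-4) {
  y <- as_binary_label(truth)
  if (sum(y == 1L) == 0L || sum(y == 0L) == 0L) {
    stop("both classes must be present")
  }
  u <- sort(unique(scores))
  k <- length(u)
  above <- if (k > 1L) u[k] + (u[k] - u[1L]) / k else u[1L] + 1
  cand <- c(u[1L], if (k > 1L) (u[-1L] + u[-k]) / 2, above)
  acc <- vapply(cand, function(ct) mean((scores >= ct) == (y == 1L)),
                numeric(1))
  best <- max(acc)
  cutoff <- cand[acc >= best][1L]
  snapped <- round(cutoff / grid_step) * grid_step
  if (isTRUE(all.equal(mean((scores >= snapped) == (y == 1L)), best))) {
    cutoff <- snapped
  }
  list(cutoff = cutoff, accuracy = best)
}
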