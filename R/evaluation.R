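normalize_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.logical(labels)) return(ifelse(labels, "Match", "Nomatch"))
  if (is.numeric(labels)) return(ifelse(labels > 0, "Match", "Nomatch"))
  stopifnot(all(labels %in% c("Match", "Nomatch")))
  labels
}

#' Confusion counts at a probability threshold
#'
#' Predicted Match iff probability is strictly greater than the threshold
#' (matching the screening rule "passed the threshold of 0.5").
#'
#' @param labels Match/Nomatch vector (factor, character, logical or 0/1).
#' @param probabilities Match-class probabilities.
#' @param threshold decision threshold (default 0.5).
#' @return list with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(labels, probabilities, threshold = 0.5) {
  labels <- normalize_labels(labels)
  stopifnot(length(labels) == length(probabilities))
  pred <- probabilities > threshold
  pos <- labels == "Match"
  list(tp = sum(pred & pos), fp = sum(pred & !pos),
       tn = sum(!pred & !pos), fn = sum(!pred & pos))
}

safe_div <- function(num, den) if (den == 0) 0 else num / den

mcc_from_counts <- function(cc) {
  with(cc, {
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    if (den == 0) 0 else (tp * tn - fp * fn) / den
  })
}

roc_points <- function(labels, probabilities) {
  pos <- labels == "Match"
  ord <- order(probabilities, decreasing = TRUE)
  p <- probabilities[ord]; y <- pos[ord]
  # group tied probabilities into single threshold steps
  grp <- cumsum(!duplicated(p))
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- !duplicated(grp, fromLast = TRUE)
  P <- sum(pos); N <- sum(!pos)
  data.frame(fpr = c(0, fp[last] / N), tpr = c(0, tp[last] / P))
}

pr_points <- function(labels, probabilities) {
  pos <- labels == "Match"
  ord <- order(probabilities, decreasing = TRUE)
  p <- probabilities[ord]; y <- pos[ord]
  grp <- cumsum(!duplicated(p))
  tp <- cumsum(y); n_pred <- seq_along(y)
  last <- !duplicated(grp, fromLast = TRUE)
  P <- sum(pos)
  data.frame(recall = tp[last] / P, precision = tp[last] / n_pred[last])
}

trapezoid <- function(x, y) {
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Imbalance-aware evaluation report
#'
#' Computes the full threshold-metric suite (MCC, F1, PPV, TPR, FPR, TNR,
#' FNR, balanced accuracy, Cohen's kappa, mean misclassification error,
#' accuracy) at the given threshold, plus rank metrics: the ROC and
#' precision-recall curves swept over the probability ranking with
#' trapezoidal AUCs. Degenerate confusion rows (zero denominators) yield 0
#' with a flag rather than NaN. With single-class labels the rank metrics
#' are reported as `NA`.
#'
#' @inheritParams confusion_counts
#' @return an `eval_report` list.
#' @export
compute_metrics <- function(labels, probabilities, threshold = 0.5) {
  labels <- normalize_labels(labels)
  stopifnot(length(labels) == length(probabilities))
  cc <- confusion_counts(labels, probabilities, threshold)
  P <- cc$tp + cc$fn; N <- cc$tn + cc$fp
  tpr <- safe_div(cc$tp, P)
  tnr <- safe_div(cc$tn, N)
  ppv <- safe_div(cc$tp, cc$tp + cc$fp)
  fpr <- safe_div(cc$fp, N)
  fnr <- safe_div(cc$fn, P)
  acc <- (cc$tp + cc$tn) / length(labels)
  f1 <- safe_div(2 * ppv * tpr, ppv + tpr)
  # Cohen's kappa
  pe <- ((cc$tp + cc$fp) * P + (cc$fn + cc$tn) * N) / length(labels)^2
  kappa <- if (pe == 1) 0 else (acc - pe) / (1 - pe)

  both <- P > 0 && N > 0
  if (both) {
    roc <- roc_points(labels, probabilities)
    pr <- pr_points(labels, probabilities)
    auc_roc <- trapezoid(roc$fpr, roc$tpr)
    auc_pr <- trapezoid(pr$recall, pr$precision)
  } else {
    roc <- pr <- NULL
    auc_roc <- auc_pr <- NA_real_
  }

  structure(list(
    confusion = cc,
    mcc = mcc_from_counts(cc), f1 = f1, ppv = ppv, tpr = tpr, fpr = fpr,
    tnr = tnr, fnr = fnr, bac = (tpr + tnr) / 2, kappa = kappa,
    mmce = 1 - acc, acc = acc,
    roc_points = roc, pr_points = pr,
    auc_roc = auc_roc, auc_pr = auc_pr,
    threshold = threshold,
    single_class = !both
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> mcc=%.3f f1=%.3f ppv=%.3f tpr=%.3f auc_roc=%s auc_pr=%s\n",
    x$mcc, x$f1, x$ppv, x$tpr,
    ifelse(is.na(x$auc_roc), "NA", sprintf("%.3f", x$auc_roc)),
    ifelse(is.na(x$auc_pr), "NA", sprintf("%.3f", x$auc_pr))))
  invisible(x)
}
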