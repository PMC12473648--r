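#' Confusion counts for binary fall detection
#'
#' `fall` is the positive class.
#'
#' @param truth,pred equal-length binary label vectors (factor/character with
#'   levels `no_fall`/`fall`, or logical, or 0/1).
#' @return list of class `confusion_counts` with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(truth, pred) {
  t_ <- as_binary_labels(truth)
  p_ <- as_binary_labels(pred)
  if (length(t_) != length(p_)) stop("truth and pred must have equal length")
  structure(list(tp = sum(t_ & p_), fp = sum(!t_ & p_),
                 tn = sum(!t_ & !p_), fn = sum(t_ & !p_)),
            class = "confusion_counts")
}

as_binary_labels <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(x == 1)
  }
  x <- as.character(x)
  if (!all(x %in% CLASS_LEVELS)) {
    stop("labels must be 'no_fall'/'fall' (or logical / 0-1)")
  }
  x == "fall"
}

#' Confusion-matrix metrics
#'
#' Accuracy, sensitivity (recall on falls), specificity, precision and
#' F1-score, the standard five ratios of the 2 x 2 confusion matrix.
#' Undefined ratios (zero denominator) are reported as `NaN` with a warning,
#' never silently as 0.
#'
#' @param counts a [confusion()] result (or a list with `tp`, `fp`, `tn`,
#'   `fn`).
#' @return list of class `eval_metrics` with the five proportions.
#' @export
classification_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  if (tp + fp + tn + fn < 1) stop("empty confusion table")
  safe_div <- function(num, den, name) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator); reporting NaN", name))
      return(NaN)
    }
    num / den
  }
  accuracy <- (tp + tn) / (tp + tn + fp + fn)
  sensitivity <- safe_div(tp, tp + fn, "sensitivity")
  specificity <- safe_div(tn, tn + fp, "specificity")
  precision <- safe_div(tp, tp + fp, "precision")
  f1 <- if (is.nan(precision) || is.nan(sensitivity) ||
            (precision + sensitivity) == 0) {
    warning("F1 undefined; reporting NaN")
    NaN
  } else 2 * precision * sensitivity / (precision + sensitivity)
  structure(list(accuracy = accuracy, sensitivity = sensitivity,
                 specificity = specificity, precision = precision, f1 = f1),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  for (m in names(x)) cat(sprintf("%-12s %s\n", m, format_percent(x[[m]])))
  invisible(x)
}

#' Format a proportion as a percentage, one decimal
#' @param p proportion in `[0, 1]`.
#' @return character, e.g. `"97.7%"`.
#' @export
format_percent <- function(p) sprintf("%.1f%%", 100 * p)

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over every distinct score plus a `+Inf`
#' sentinel, plotting sensitivity (true-positive rate) against the
#' false-positive rate (1 - specificity); the area under the curve is
#' computed by the trapezoidal rule. Constant scores give the chance
#' diagonal (AUC 0.5).
#'
#' @param truth binary labels (both classes must be present).
#' @param scores fall probabilities/scores in `[0, 1]` (any finite scores
#'   accepted).
#' @return list with `roc_points` (data frame `threshold`, `fpr`, `tpr`,
#'   descending thresholds) and `auc`.
#' @export
roc_and_auc <- function(truth, scores) {
  t_ <- as_binary_labels(truth)
  if (length(t_) != length(scores)) stop("truth and scores must have equal length")
  if (!all(is.finite(scores))) stop("scores must be finite")
  P <- sum(t_); N <- sum(!t_)
  if (P == 0 || N == 0) stop("ROC needs both classes present in truth")
  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- fpr <- numeric(length(thresholds))
  for (i in seq_along(thresholds)) {
    pred <- scores >= thresholds[i]
    tpr[i] <- sum(pred & t_) / P
    fpr[i] <- sum(pred & !t_) / N
  }
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(roc_points = data.frame(threshold = thresholds, fpr = fpr, tpr = tpr),
       auc = auc)
}

#' Full evaluation report for binary fall detection
#'
#' @param truth binary labels.
#' @param scores fall probabilities.
#' @param threshold decision threshold for the confusion-based metrics.
#' @return list of class `evaluation_report`: `counts`, `metrics` (as
#'   proportions), `percent` (formatted percentages), `roc_points`, `auc`.
#' @export
evaluation_report <- function(truth, scores, threshold = 0.5) {
  pred <- scores >= threshold
  counts <- confusion(truth, pred)
  metrics <- classification_metrics(counts)
  roc <- roc_and_auc(truth, scores)
  structure(list(counts = counts, metrics = metrics,
                 percent = lapply(metrics, format_percent),
                 roc_points = roc$roc_points, auc = roc$auc,
                 threshold = threshold),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Evaluation at threshold %.2f (n = %d):\n", x$threshold,
              x$counts$tp + x$counts$fp + x$counts$tn + x$counts$fn))
  print(x$metrics)
  cat(sprintf("AUC          %.3f\n", x$auc))
  invisible(x)
}

report_to_list <- function(report) {
  list(accuracy = report$metrics$accuracy,
       sensitivity = report$metrics$sensitivity,
       specificity = report$metrics$specificity,
       precision = report$metrics$precision,
       f1 = report$metrics$f1,
       auc = report$auc,
       percent = report$percent,
       counts = unclass(report$counts),
       threshold = report$threshold)
}
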