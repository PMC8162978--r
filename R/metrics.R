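#' Classification metrics with mutant as the positive class
#'
#' Confusion-matrix metrics for binary mutation-status prediction. The
#' mutant (minority) class is always the positive class, so sensitivity is
#' the fraction of mutant samples detected. If the true labels contain
#' only one class, the undefined ratio is reported as `NA` with a warning
#' — never silently coerced to 0 or 1, which would make degenerate folds
#' look artificially good.
#'
#' @param labels true labels (anything [feature_table()] accepts:
#'   `"mutant"`/`"wildtype"`, factor, or 0/1 with 1 = mutant).
#' @param predicted predicted labels, same conventions.
#' @return A list of class `metrics_report`: `accuracy`, `sensitivity`,
#'   `specificity`, `auc` (NA until filled by [auc_score()] callers) and
#'   `counts` (TP, FP, TN, FN).
#' @examples
#' confusion_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0))
#' @export
confusion_metrics <- function(labels, predicted) {
  y <- as_mutation_label(labels)
  p <- as_mutation_label(predicted)
  if (length(y) != length(p)) stop("'labels' and 'predicted' lengths differ")
  tp <- sum(y == "mutant" & p == "mutant")
  fn <- sum(y == "mutant" & p == "wildtype")
  tn <- sum(y == "wildtype" & p == "wildtype")
  fp <- sum(y == "wildtype" & p == "mutant")
  sens <- if (tp + fn > 0) tp / (tp + fn) else {
    warning("no positive (mutant) samples: sensitivity undefined")
    NA_real_
  }
  spec <- if (tn + fp > 0) tn / (tn + fp) else {
    warning("no negative (wildtype) samples: specificity undefined")
    NA_real_
  }
  structure(list(
    accuracy = (tp + tn) / length(y),
    sensitivity = sens,
    specificity = spec,
    auc = NA_real_,
    counts = c(TP = tp, FP = fp, TN = tn, FN = fn)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "accuracy %.3f | sensitivity %.3f | specificity %.3f | AUC %s\n",
    x$accuracy, x$sensitivity, x$specificity,
    if (is.na(x$auc)) "-" else sprintf("%.3f", x$auc)
  ))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Rank-statistic AUC: the fraction of (mutant, wildtype) pairs in which
#' the mutant sample receives the higher score, ties counted half. This
#' equals the trapezoidal area under the ROC curve and is invariant under
#' any strictly increasing transform of the scores.
#'
#' @param labels true labels, both classes present.
#' @param scores minority-class (mutant) pseudo-probabilities or any
#'   real-valued scores.
#' @return AUC in \[0, 1\].
#' @examples
#' auc_score(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.2)) # 0.75
#' @export
auc_score <- function(labels, scores) {
  y <- as_mutation_label(labels) == "mutant"
  if (length(y) != length(scores)) stop("'labels' and 'scores' lengths differ")
  n1 <- sum(y)
  n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Full metrics report from labels, predictions and scores
#'
#' @inheritParams confusion_metrics
#' @param scores mutant pseudo-probabilities used for the AUC.
#' @return A `metrics_report` with the `auc` slot filled.
#' @export
metrics_report <- function(labels, predicted, scores) {
  rep <- confusion_metrics(labels, predicted)
  rep$auc <- auc_score(labels, scores)
  rep
}
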