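# Confusion counts, threshold metrics, and rank-statistic ROC / AUC.

#' Confusion counts
#'
#' @param y_true,y_pred Equal-length binary 0/1 vectors; positives are
#'   label 1.
#' @return Named integer vector `c(TP, TN, FP, FN)`.
#' @export
#' @examples
#' confusion(c(1, 1, 0, 0), c(1, 0, 0, 1))
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1))) {
    stop("labels must be binary 0/1", call. = FALSE)
  }
  c(TP = sum(y_true == 1 & y_pred == 1),
    TN = sum(y_true == 0 & y_pred == 0),
    FP = sum(y_true == 0 & y_pred == 1),
    FN = sum(y_true == 1 & y_pred == 0))
}

#' Threshold classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)` and F1
#' `2*precision*recall/(precision+recall)`.  A metric whose denominator is
#' zero is undefined and returned as `NA` with a warning — never silently 0.
#'
#' @param TP,TN,FP,FN Non-negative confusion counts (or a single named
#'   vector from [confusion()] passed as `TP`).
#' @return Named numeric vector with elements `accuracy`, `precision`,
#'   `recall`, `specificity`, `f1`.
#' @export
#' @examples
#' classification_metrics(TP = 30403, TN = 14593, FP = 7878, FN = 1560)
classification_metrics <- function(TP, TN = NULL, FP = NULL, FN = NULL) {
  if (is.null(TN) && length(TP) == 4L && !is.null(names(TP))) {
    counts <- TP
    TP <- counts[["TP"]]; TN <- counts[["TN"]]
    FP <- counts[["FP"]]; FN <- counts[["FN"]]
  }
  counts <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(counts < 0)) stop("negative confusion count", call. = FALSE)
  if (sum(counts) == 0) stop("all confusion counts are zero", call. = FALSE)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (0/0 denominator); returning NA",
              call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  precision <- safe_div(TP, TP + FP, "precision")
  recall <- safe_div(TP, TP + FN, "recall")
  f1 <- if (is.na(precision) || is.na(recall)) {
    warning("f1 undefined; returning NA", call. = FALSE)
    NA_real_
  } else {
    safe_div(2 * precision * recall, precision + recall, "f1")
  }
  c(accuracy = (TP + TN) / sum(counts),
    precision = precision,
    recall = recall,
    specificity = safe_div(TN, TN + FP, "specificity"),
    f1 = f1)
}

#' Rank-statistic ROC AUC
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, with ties counted one half — the Mann-Whitney statistic,
#' equal to the trapezoidal area under the ROC curve over all thresholds.
#'
#' @param scores Real-valued scores, larger meaning more positive.
#' @param y_true Binary 0/1 labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))
roc_auc <- function(scores, y_true) {
  stopifnot(length(scores) == length(y_true))
  y_true <- as.integer(y_true)
  n1 <- sum(y_true == 1L)
  n0 <- sum(y_true == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present to compute AUC", call. = FALSE)
  }
  r <- rank(scores)  # average ranks handle ties as 1/2
  (sum(r[y_true == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' Sweeps all distinct score thresholds (the point at a threshold counts a
#' prediction as positive when `score >= threshold`) and records the
#' operating points.
#'
#' @inheritParams roc_auc
#' @return Data frame with columns `threshold`, `fpr`, `tpr`, ordered from
#'   the all-negative corner (0, 0) to the all-positive corner (1, 1).
#' @export
roc_curve <- function(scores, y_true) {
  y_true <- as.integer(y_true)
  n1 <- sum(y_true == 1L)
  n0 <- sum(y_true == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- y_true[ord]
  cum_tp <- cumsum(y == 1L)
  cum_fp <- cumsum(y == 0L)
  last <- c(s[-1] != s[-length(s)], TRUE)  # group tied scores
  data.frame(threshold = c(Inf, s[last]),
             fpr = c(0, cum_fp[last] / n0),
             tpr = c(0, cum_tp[last] / n1))
}

#' Evaluate a trained model on a test set
#'
#' @param model A `trained_model`.
#' @param x Test feature matrix matching the model's contract.
#' @param y Binary 0/1 test labels.
#' @param threshold Optional score threshold for the label decision.
#' @return An `eval_report`: confusion counts, the five threshold metrics,
#'   the rank-statistic AUC, and the ROC points.
#' @export
evaluate_model <- function(model, x, y, threshold = NULL) {
  scores <- decision_scores(model, x)
  if (is.null(threshold)) threshold <- model$threshold
  y_pred <- as.integer(scores > threshold)
  counts <- confusion(y, y_pred)
  structure(list(counts = counts,
                 metrics = classification_metrics(counts),
                 auc_roc = roc_auc(scores, y),
                 roc = roc_curve(scores, y),
                 threshold = threshold,
                 scores = scores,
                 run_log = model$run_log),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  cat(sprintf("  TP=%d TN=%d FP=%d FN=%d\n", x$counts[["TP"]],
              x$counts[["TN"]], x$counts[["FP"]], x$counts[["FN"]]))
  m <- x$metrics
  cat(sprintf("  AUC=%.3f  acc=%.3f  prec=%.3f  recall=%.3f  spec=%.3f  F1=%.3f\n",
              x$auc_roc, m[["accuracy"]], m[["precision"]], m[["recall"]],
              m[["specificity"]], m[["f1"]]))
  invisible(x)
}
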