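#' Confusion counts at a decision threshold
#'
#' Thresholds scores into binary calls (`score >= threshold` predicts the
#' positive class; ties at the threshold count as positive) and tabulates
#' them against the true labels.
#'
#' @param scores Numeric vector of classifier scores.
#' @param labels Integer 0/1 vector of true labels, same length.
#' @param threshold Decision threshold (default 0.5).
#' @return An object of class `confusion_counts`: list with `TP`, `FP`,
#'   `TN`, `FN`.
#' @export
confusion <- function(scores, labels, threshold = 0.5) {
  if (length(scores) == 0L) abort("empty input")
  if (length(scores) != length(labels)) {
    abort("`scores` and `labels` must have equal length")
  }
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) abort("labels must be 0/1")
  pred <- as.integer(scores >= threshold)
  confusion_counts(
    TP = sum(pred == 1L & labels == 1L),
    FP = sum(pred == 1L & labels == 0L),
    TN = sum(pred == 0L & labels == 0L),
    FN = sum(pred == 0L & labels == 1L)
  )
}

#' @rdname confusion
#' @param TP,FP,TN,FN Non-negative integer counts (used to enter counts
#'   reported elsewhere, e.g. from a published comparison table).
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  counts <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("confusion counts must be non-negative integers")
  }
  structure(lapply(as.list(counts), as.integer), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP %d | FP %d | TN %d | FN %d\n",
              x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Threshold metrics from confusion counts
#'
#' Computes the four standard residue-classification metrics:
#' sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/total`, and the Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. When any
#' factor under the MCC square root is zero the MCC is reported as 0
#' with a warning. Values are exact; round only for presentation.
#'
#' @param counts A `confusion_counts` object.
#' @return A one-row tibble with columns `sensitivity`, `specificity`,
#'   `accuracy`, `mcc`.
#' @export
#' @examples
#' compute_metrics(confusion_counts(TP = 26, FP = 80, TN = 3647, FN = 5))
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  total <- TP + FP + TN + FN
  if (total == 0L) abort("all confusion counts are zero")
  denom2 <- as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (denom2 == 0) {
    warning("a factor of the MCC denominator is zero; reporting MCC = 0")
    0
  } else {
    (as.numeric(TP) * TN - as.numeric(FP) * FN) / sqrt(denom2)
  }
  tibble::tibble(
    sensitivity = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
    specificity = if (TN + FP > 0) TN / (TN + FP) else NA_real_,
    accuracy = (TP + TN) / total,
    mcc = mcc
  )
}

#' Exact ROC AUC and ROC curve
#'
#' The AUC is computed exactly as the Mann-Whitney pair statistic: the
#' fraction of (positive, negative) pairs where the positive outscores
#' the negative, ties counted one half (midrank formulation). The `(fpr,
#' tpr)` curve, one point per distinct threshold, is returned for
#' plotting; its trapezoidal area equals the pair statistic.
#'
#' @inheritParams confusion
#' @return An object of class `roc_result`: list with `auc` and `curve`
#'   (a tibble of `threshold`, `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) {
    abort("`scores` and `labels` must have equal length")
  }
  if (!all(labels %in% c(0L, 1L))) abort("labels must be 0/1")
  P <- sum(labels == 1L)
  N <- sum(labels == 0L)
  if (P == 0L || N == 0L) {
    abort("ROC AUC needs both classes present")
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - P * (P + 1) / 2) / (as.numeric(P) * N)

  ord <- order(scores, decreasing = TRUE)
  s_sorted <- scores[ord]
  l_sorted <- labels[ord]
  keep <- c(diff(s_sorted) != 0, TRUE)   # last index of each tie group
  tpr <- cumsum(l_sorted)[keep] / P
  fpr <- cumsum(1L - l_sorted)[keep] / N
  curve <- tibble::tibble(
    threshold = c(Inf, s_sorted[keep]),
    fpr = c(0, fpr),
    tpr = c(0, tpr)
  )
  structure(list(auc = auc, curve = curve), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d curve points)\n",
              x$auc, nrow(x$curve)))
  invisible(x)
}

#' @describeIn roc_auc The ROC curve points as a tibble.
#' @param x A `roc_result`.
#' @param ... Unused.
#' @method tidy roc_result
#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @describeIn roc_auc One-row tibble holding the AUC.
#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) tibble::tibble(auc = x$auc)

#' @describeIn roc_auc ROC curve plot.
#' @param object A `roc_result`.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      title = sprintf("ROC curve (AUC = %.4f)", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Full metric report for scored residues
#'
#' Convenience wrapper combining [confusion()], [compute_metrics()] and
#' [roc_auc()] into the one-row report used throughout the ablation
#' tables.
#'
#' @inheritParams confusion
#' @return A one-row tibble: `sensitivity`, `specificity`, `accuracy`,
#'   `mcc`, `auc`, plus the four confusion counts.
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5) {
  cc <- confusion(scores, labels, threshold)
  m <- compute_metrics(cc)
  m$auc <- roc_auc(scores, labels)$auc
  dplyr::bind_cols(m, tibble::as_tibble(unclass(cc)))
}

#' Youden-J-optimal threshold
#'
#' Returns the score threshold maximizing `sensitivity + specificity - 1`
#' on the given (typically validation) data. Provided as an optional
#' alternative to the default 0.5 threshold; ties resolve to the highest
#' qualifying threshold.
#'
#' @inheritParams confusion
#' @return A single numeric threshold.
#' @export
youden_threshold <- function(scores, labels) {
  r <- roc_auc(scores, labels)
  j <- r$curve$tpr - r$curve$fpr
  best <- which(j == max(j))[1]
  t <- r$curve$threshold[best]
  if (!is.finite(t)) t <- max(scores) + 1
  t
}

#' Greedy window-combination order
#'
#' Given candidate single window sizes and their single-window AUCs,
#' returns the nested combinations to evaluate: windows are ranked by
#' descending AUC and combinations grow one window at a time in that
#' order (best alone, then best two, ...).
#'
#' @param windows Integer vector of window sizes.
#' @param aucs Numeric vector of their single-window AUCs.
#' @return A list of integer vectors, one combination per element.
#' @export
#' @examples
#' greedy_combinations(c(2, 4, 6), c(0.97, 0.98, 0.96))
greedy_combinations <- function(windows, aucs) {
  stopifnot(length(windows) == length(aucs))
  ord <- order(aucs, decreasing = TRUE)
  lapply(seq_along(ord), function(i) as.integer(windows[ord[seq_len(i)]]))
}
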