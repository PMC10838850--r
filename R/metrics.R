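#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision: with items sorted by decreasing score and
#' thresholds at each distinct score value, `AUPRC = sum_k (R_k - R_{k-1}) *
#' P_k`. No interpolation is applied. Tied scores are treated as a single
#' threshold. The anomalous class (label 1) is the positive class; with a
#' constant score the value equals the positive prevalence.
#'
#' @param labels 0/1 vector of true labels (1 = positive/anomalous).
#' @param scores numeric vector of positive-class scores.
#' @return Scalar in `[0, 1]`.
#' @examples
#' auprc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1))
#' @export
auprc <- function(labels, scores) {
  if (length(labels) != length(scores))
    stop("'labels' and 'scores' must have equal length", call. = FALSE)
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L)))
    stop("'labels' must be 0/1", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("AUPRC undefined: both classes must be present", call. = FALSE)
  o <- order(scores, decreasing = TRUE)
  l <- labels[o]; s <- scores[o]
  tp <- cumsum(l); fp <- cumsum(1L - l)
  ends <- c(which(diff(s) != 0), length(s))     # last index of each tied group
  P <- tp[ends] / (tp[ends] + fp[ends])
  R <- tp[ends] / sum(l)
  sum(diff(c(0, R)) * P)
}

#' F1 score
#'
#' `2 TP / (2 TP + FP + FN)` with anomalous (label 1) as the positive class;
#' defined as 0 when the denominator is 0 (no positives anywhere).
#'
#' @param labels 0/1 vector of true labels.
#' @param predicted 0/1 vector of predicted labels.
#' @return Scalar in `[0, 1]`.
#' @export
f1 <- function(labels, predicted) {
  if (length(labels) != length(predicted))
    stop("'labels' and 'predicted' must have equal length", call. = FALSE)
  if (length(labels) < 1L) stop("need at least one prediction", call. = FALSE)
  labels <- as.integer(labels); predicted <- as.integer(predicted)
  tp <- sum(labels == 1L & predicted == 1L)
  fp <- sum(labels == 0L & predicted == 1L)
  fn <- sum(labels == 1L & predicted == 0L)
  denom <- 2 * tp + fp + fn
  if (denom == 0) return(0)
  2 * tp / denom
}

#' Mean and standard deviation of metrics across folds
#'
#' Arithmetic mean and sample (n-1) standard deviation per metric column.
#'
#' @param per_fold_metrics data frame with one row per fold and numeric
#'   metric columns (e.g. `auprc`, `f1`); at least two folds.
#' @return Data frame with columns `metric`, `mean`, `sd`, `n_folds`.
#' @export
cross_fold_summary <- function(per_fold_metrics) {
  stopifnot(is.data.frame(per_fold_metrics))
  num <- vapply(per_fold_metrics, is.numeric, TRUE) &
    !names(per_fold_metrics) %in% "fold"
  if (nrow(per_fold_metrics) < 2L)
    stop("need at least two folds to summarize", call. = FALSE)
  cols <- names(per_fold_metrics)[num]
  data.frame(
    metric = cols,
    mean = vapply(cols, function(c) mean(per_fold_metrics[[c]]), 0),
    sd = vapply(cols, function(c) stats::sd(per_fold_metrics[[c]]), 0),
    n_folds = nrow(per_fold_metrics), row.names = NULL)
}
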