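#' Canonical metric order
#'
#' The seven evaluation metrics in their canonical (frozen) radar order:
#' F1, Accuracy, Balanced Accuracy, Precision, Recall, Average Precision,
#' ROC-AUC. The cumulative performance score depends on this order up to
#' cyclic rotation, so it is fixed here and echoed in all outputs.
#'
#' @return character vector of metric names.
#' @export
metric_names <- function() {
  c("F1", "Accuracy", "Balanced_Accuracy", "Precision", "Recall",
    "Average_Precision", "ROC_AUC")
}

#' Binary classification metrics for the positive class
#'
#' Computes the seven-metric vector from true labels, predicted labels and a
#' continuous score (probability or decision value, larger = more positive).
#' F1/Precision/Recall are for the positive class (not macro-averaged);
#' degenerate denominators yield 0. ROC-AUC is the rank (Mann-Whitney)
#' statistic with tie correction; Average Precision is the step-wise
#' precision-recall summation over decreasing score thresholds. When the test
#' fold contains a single class, ROC-AUC and Average Precision are undefined
#' and reported as 0.5 and the positive prevalence respectively.
#'
#' @param truth logical/0-1 vector (TRUE = positive class).
#' @param predicted logical/0-1 vector of hard predictions.
#' @param score numeric score vector (larger favours the positive class).
#' @return named numeric vector over [metric_names()].
#' @export
binary_metrics <- function(truth, predicted, score) {
  truth <- as.logical(truth); predicted <- as.logical(predicted)
  tp <- sum(truth & predicted); fp <- sum(!truth & predicted)
  fn <- sum(truth & !predicted); tn <- sum(!truth & !predicted)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  acc <- (tp + tn) / length(truth)
  tnr <- if (tn + fp > 0) tn / (tn + fp) else 0
  tpr <- rec
  bacc <- if (any(truth) && any(!truth)) (tpr + tnr) / 2 else acc
  c(F1 = f1, Accuracy = acc, Balanced_Accuracy = bacc, Precision = prec,
    Recall = rec, Average_Precision = average_precision(truth, score),
    ROC_AUC = roc_auc(truth, score))
}

#' @rdname binary_metrics
#' @export
roc_auc <- function(truth, score) {
  truth <- as.logical(truth)
  np <- sum(truth); nn <- sum(!truth)
  if (np == 0 || nn == 0) return(0.5)
  r <- rank(score)
  (sum(r[truth]) - np * (np + 1) / 2) / (np * nn)
}

#' @rdname binary_metrics
#' @export
average_precision <- function(truth, score) {
  truth <- as.logical(truth)
  np <- sum(truth)
  if (np == 0) return(0)
  if (all(truth)) return(1)
  # process thresholds in decreasing score order, ties as one block
  ord <- order(-score)
  t_sorted <- truth[ord]; s_sorted <- score[ord]
  blocks <- cumsum(!duplicated(s_sorted))
  tp <- cumsum(t_sorted); n_pred <- seq_along(t_sorted)
  last_of_block <- !duplicated(blocks, fromLast = TRUE)
  tp_b <- tp[last_of_block]; n_b <- n_pred[last_of_block]
  recall <- tp_b / np
  precision <- tp_b / n_b
  sum(diff(c(0, recall)) * precision)
}

# aggregate a folds x metrics matrix into mean/sd rows
aggregate_metrics <- function(fold_matrix) {
  mu <- colMeans(fold_matrix)
  sdv <- apply(fold_matrix, 2, sd)
  if (nrow(fold_matrix) == 1) sdv[] <- 0
  list(mean = mu, sd = sdv)
}
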