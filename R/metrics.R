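# Agreement metrics for discrete score mapping and tile classification:
# mean absolute error, unweighted Cohen's kappa, support-weighted
# precision/recall/F1, accuracy, and confusion matrices.

#' Mean absolute error
#'
#' @param predicted,truth Equal-length numeric score vectors.
#' @return Mean of |predicted - truth|.
#' @examples
#' mean_absolute_error(c(1, 2), c(1, 3))  # 0.5
#' @export
mean_absolute_error <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth), length(truth) > 0)
  mean(abs(predicted - truth))
}

#' Unweighted Cohen's kappa
#'
#' \eqn{\kappa = (p_o - p_e) / (1 - p_e)} with observed agreement p_o and
#' chance agreement p_e from the marginal products. When both raters are
#' constant and identical (p_e = 1), kappa is 1 by convention.
#'
#' @param predicted,truth Equal-length score vectors.
#' @return Kappa in \[-1, 1\].
#' @export
cohen_kappa <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth), length(truth) > 0)
  labels <- sort(unique(c(predicted, truth)))
  n <- length(truth)
  po <- mean(predicted == truth)
  pp <- vapply(labels, function(l) sum(predicted == l), 0) / n
  pt <- vapply(labels, function(l) sum(truth == l), 0) / n
  pe <- sum(pp * pt)
  if (abs(1 - pe) < 1e-15) return(if (po == 1) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Confusion matrix
#'
#' Entry (i, j) counts records with truth i and prediction j.
#'
#' @param predicted,truth Equal-length score vectors.
#' @param labels Label set covering all observed values (default: their
#'   union, sorted).
#' @return Square count matrix, rows = truth, columns = predicted.
#' @export
confusion_matrix <- function(predicted, truth,
                             labels = sort(unique(c(predicted, truth)))) {
  stopifnot(length(predicted) == length(truth))
  if (!all(predicted %in% labels) || !all(truth %in% labels)) {
    stop("values outside the label set", call. = FALSE)
  }
  table(factor(truth, levels = labels),
        factor(predicted, levels = labels),
        dnn = c("truth", "predicted"))
}

#' Support-weighted precision, recall, F1, and accuracy
#'
#' Per-class precision/recall/F1 are averaged with weights proportional
#' to true-class support. A class never predicted has precision 0; a
#' class with zero precision+recall has F1 0.
#'
#' @param predicted,truth Equal-length score vectors.
#' @param labels Label set (default: observed union).
#' @return Named list: `weighted_precision`, `weighted_recall`,
#'   `weighted_f1`, `accuracy`.
#' @export
weighted_prf_accuracy <- function(predicted, truth,
                                  labels = sort(unique(c(predicted, truth)))) {
  cm <- confusion_matrix(predicted, truth, labels)
  support <- rowSums(cm)
  pred_tot <- colSums(cm)
  tp <- diag(cm)
  prec <- ifelse(pred_tot > 0, tp / pred_tot, 0)
  rec <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  w <- support / sum(support)
  list(weighted_precision = sum(w * prec),
       weighted_recall = sum(w * rec),
       weighted_f1 = sum(w * f1),
       accuracy = sum(tp) / sum(cm))
}

#' Full agreement-metric bundle
#'
#' All metrics reported for score mapping: MAE, unweighted Cohen's kappa,
#' weighted precision/recall/F1, accuracy, and the confusion matrix.
#'
#' @param predicted,truth Equal-length score vectors.
#' @param labels Label set (default: observed union).
#' @return A `metric_bundle` list.
#' @export
metric_bundle <- function(predicted, truth,
                          labels = sort(unique(c(predicted, truth)))) {
  prf <- weighted_prf_accuracy(predicted, truth, labels)
  structure(list(
    mae = mean_absolute_error(predicted, truth),
    cohen_kappa = cohen_kappa(predicted, truth),
    weighted_f1 = prf$weighted_f1,
    weighted_precision = prf$weighted_precision,
    weighted_recall = prf$weighted_recall,
    accuracy = prf$accuracy,
    confusion = confusion_matrix(predicted, truth, labels),
    n = length(truth)), class = "metric_bundle")
}

#' @export
print.metric_bundle <- function(x, ...) {
  cat(sprintf(
    "<metric_bundle> n=%d  MAE %.3f  kappa %.3f  acc %.3f  wF1 %.3f  wP %.3f  wR %.3f\n",
    x$n, x$mae, x$cohen_kappa, x$accuracy, x$weighted_f1,
    x$weighted_precision, x$weighted_recall))
  invisible(x)
}

#' Write a metric bundle to JSON (and the confusion matrix to CSV)
#'
#' @param bundle A [metric_bundle()].
#' @param path JSON output path; the confusion matrix goes to the same
#'   path with suffix `_confusion.csv`.
#' @return The JSON path, invisibly.
#' @export
write_metrics <- function(bundle, path) {
  scalars <- bundle[c("mae", "cohen_kappa", "weighted_f1",
                      "weighted_precision", "weighted_recall", "accuracy",
                      "n")]
  jsonlite::write_json(scalars, path, auto_unbox = TRUE, digits = NA)
  cmpath <- sub("\\.json$", "", path)
  utils::write.csv(as.data.frame.matrix(bundle$confusion),
                   paste0(cmpath, "_confusion.csv"))
  invisible(path)
}
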