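# Binary evaluation harness: confusion matrix, the standard metric panel
# (accuracy, prevalence, precision, recall/sensitivity, F1, specificity,
# AUC) and ROC computation, with a rank-based Mann-Whitney AUC as an
# internal cross-check of the trapezoidal estimate.

#' Binary confusion matrix
#'
#' Counts with positive class `1`.
#'
#' @param y_true,y_pred equal-length 0/1 vectors.
#' @return object of class `confusion` with integer fields `tp`, `fp`,
#'   `fn`, `tn`.
#' @export
confusion_binary <- function(y_true, y_pred) {
  if (length(y_true) == 0L) stop("empty input", call. = FALSE)
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  if (!all(y_true %in% 0:1) || !all(y_pred %in% 0:1)) {
    stop("labels must be 0/1; binarize first", call. = FALSE)
  }
  structure(list(tp = sum(y_true == 1L & y_pred == 1L),
                 fp = sum(y_true == 0L & y_pred == 1L),
                 fn = sum(y_true == 1L & y_pred == 0L),
                 tn = sum(y_true == 0L & y_pred == 0L)),
            class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2L, 2L,
              dimnames = list(truth = c("1", "0"), predicted = c("1", "0")))
  print(m)
  invisible(x)
}

#' Multi-class confusion matrix
#'
#' The K x K pre-binarization view (rows = truth, columns = predicted);
#' correct predictions sit on the diagonal.
#'
#' @param y_true,y_pred equal-length label vectors.
#' @return an integer matrix.
#' @export
confusion_multiclass <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  lev <- sort(unique(c(y_true, y_pred)))
  as.matrix(table(truth = factor(y_true, lev), predicted = factor(y_pred, lev)))
}

#' Metric panel from a confusion matrix
#'
#' Computes the full panel reported by the experiment harness: accuracy,
#' prevalence, precision, recall, F1, specificity and sensitivity (recall
#' and sensitivity are the same quantity for binary classification and are
#' reported as one value under both names). A metric whose denominator is
#' zero is reported as 0 and its name recorded in the `degenerate` field,
#' so sweeps over many folds never abort on a degenerate partition.
#'
#' @param cm a [confusion_binary()] result.
#' @param auc optional AUC to carry into the report (from [roc_auc()]).
#' @param split_label optional label (e.g. `"Training"`, `"Testing"`).
#' @return object of class `metrics_report`.
#' @export
classification_metrics <- function(cm, auc = NA_real_, split_label = "") {
  stopifnot(inherits(cm, "confusion"))
  n <- cm$tp + cm$fp + cm$fn + cm$tn
  if (n == 0L) stop("confusion matrix has zero total", call. = FALSE)
  degenerate <- character(0L)
  ratio <- function(num, den, name) {
    if (den == 0) {
      degenerate <<- c(degenerate, name)
      return(0)
    }
    num / den
  }
  precision <- ratio(cm$tp, cm$tp + cm$fp, "precision")
  recall <- ratio(cm$tp, cm$tp + cm$fn, "recall")
  specificity <- ratio(cm$tn, cm$tn + cm$fp, "specificity")
  f1 <- if (precision + recall == 0) {
    degenerate <- c(degenerate, "f1")
    0
  } else 2 * precision * recall / (precision + recall)
  if (length(degenerate) > 0L) {
    warning(sprintf("zero-denominator metric(s) reported as 0: %s",
                    paste(unique(degenerate), collapse = ", ")), call. = FALSE)
  }
  structure(list(accuracy = (cm$tp + cm$tn) / n,
                 prevalence = (cm$tp + cm$fn) / n,
                 precision = precision, recall = recall, f1 = f1,
                 specificity = specificity, sensitivity = recall,
                 auc = auc, n_samples = n, split_label = split_label,
                 degenerate = unique(degenerate), confusion = cm),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report>%s n=%d\n",
              if (nzchar(x$split_label)) paste0(" ", x$split_label) else "",
              x$n_samples))
  vals <- c(accuracy = x$accuracy, prevalence = x$prevalence,
            precision = x$precision, recall = x$recall, f1 = x$f1,
            specificity = x$specificity, sensitivity = x$sensitivity,
            auc = x$auc)
  for (k in names(vals)) cat(sprintf("  %-12s %.4f\n", k, vals[[k]]))
  invisible(x)
}

#' ROC curve and trapezoidal AUC
#'
#' Sweeps every distinct score as a threshold (ties grouped into a single
#' step), accumulating false/true positive rates from (0, 0) to (1, 1), and
#' integrates the curve by the trapezoid rule. The grouped-tie trapezoid is
#' exactly the Mann-Whitney statistic with half-credit for tied scores; see
#' [auc_rank()] for the independent rank-based computation.
#'
#' @param y_true 0/1 labels containing both classes.
#' @param scores real-valued decision scores (higher means more positive).
#' @return object of class `roc_curve` with `thresholds` (descending),
#'   `fpr`, `tpr` and `auc`.
#' @export
roc_curve <- function(y_true, scores) {
  if (length(y_true) != length(scores)) {
    stop("y_true and scores must have equal length", call. = FALSE)
  }
  if (!all(y_true %in% 0:1)) stop("labels must be 0/1", call. = FALSE)
  P <- sum(y_true == 1L)
  N <- sum(y_true == 0L)
  if (P == 0L || N == 0L) {
    stop("both classes must be present to compute a ROC curve", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- y_true[ord]
  last <- cumsum(rle(s)$lengths)      # end index of each tied score group
  tp <- cumsum(y == 1L)[last]
  fp <- cumsum(y == 0L)[last]
  tpr <- c(0, tp / P)
  fpr <- c(0, fp / N)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  structure(list(thresholds = c(Inf, s[last]), fpr = fpr, tpr = tpr,
                 auc = auc), class = "roc_curve")
}

#' Trapezoidal AUC
#'
#' @inheritParams roc_curve
#' @return the area under the ROC curve as a single number.
#' @export
roc_auc <- function(y_true, scores) roc_curve(y_true, scores)$auc

#' Rank-based (Mann-Whitney) AUC
#'
#' Computes the probability that a random positive outscores a random
#' negative, with half-credit for ties, from midranks:
#' `AUC = (sum of positive ranks - P(P+1)/2) / (P * N)`. Serves as an exact
#' independent cross-check of the trapezoidal [roc_auc()].
#'
#' @inheritParams roc_curve
#' @return the AUC as a single number.
#' @export
auc_rank <- function(y_true, scores) {
  P <- sum(y_true == 1L)
  N <- sum(y_true == 0L)
  if (P == 0L || N == 0L) {
    stop("both classes must be present to compute AUC", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[y_true == 1L]) - P * (P + 1) / 2) / (P * N)
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d points, AUC = %.4f\n", length(x$fpr), x$auc))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  plot(x$fpr, x$tpr, type = "l", xlab = "False positive rate",
       ylab = "True positive rate", xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "blue")
  invisible(x)
}

#' Export ROC points as CSV
#'
#' @param roc a `roc_curve`.
#' @param path output path; two columns `fpr`, `tpr`.
#' @return `path`, invisibly.
#' @export
write_roc_csv <- function(roc, path) {
  stopifnot(inherits(roc, "roc_curve"))
  utils::write.csv(data.frame(fpr = roc$fpr, tpr = roc$tpr), path,
                   row.names = FALSE)
  invisible(path)
}

#' Evaluate a trained model on a labeled partition
#'
#' Convenience wrapper: scores, thresholds, builds the confusion matrix,
#' computes the metric panel and the AUC in one call.
#'
#' @param model a trained binary `elm` (or any object with a
#'   `predict(type = "score")` method returning one score column).
#' @param ds an `eeg_binary` whose features are already on the model's
#'   scale.
#' @param threshold decision threshold.
#' @param split_label label carried into the report.
#' @return a `metrics_report`.
#' @export
evaluate_model <- function(model, ds, threshold = 0.5, split_label = "") {
  scores <- predict(model, ds$features, type = "score")[, 1L]
  pred <- as.integer(scores >= threshold)
  cm <- confusion_binary(ds$labels, pred)
  auc <- if (length(unique(ds$labels)) == 2L) roc_auc(ds$labels, scores)
         else NA_real_
  classification_metrics(cm, auc = auc, split_label = split_label)
}
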