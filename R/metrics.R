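#' Multiclass confusion matrix
#'
#' @param y_true,y_pred label vectors of equal positive length. Factors keep
#'   their level order; otherwise classes are ordered by first appearance in
#'   `c(y_true, y_pred)`.
#' @param classes optional explicit class order.
#' @return square integer matrix, true classes as rows, predicted as columns.
#' @export
confusion_matrix <- function(y_true, y_pred, classes = NULL) {
  if (length(y_true) != length(y_pred) || length(y_true) == 0) {
    stop("input error: y_true and y_pred must have equal positive length")
  }
  if (is.null(classes)) {
    classes <- if (is.factor(y_true)) {
      union(levels(y_true), unique(as.character(y_pred)))
    } else {
      unique(c(as.character(y_true), as.character(y_pred)))
    }
  }
  t1 <- factor(as.character(y_true), levels = classes)
  t2 <- factor(as.character(y_pred), levels = classes)
  if (anyNA(t1) || anyNA(t2)) stop("input error: labels outside class set")
  as.matrix(table(true = t1, predicted = t2))
}

per_class_f1_from_confusion <- function(cm) {
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  denom <- 2 * tp + fp + fn
  f1 <- ifelse(denom == 0, 0, 2 * tp / denom)
  names(f1) <- rownames(cm)
  f1
}

#' Classification metrics for imbalanced multiclass problems
#'
#' Per-class F1 is `2 * precision * recall / (precision + recall)`, set to 0
#' when the denominator is 0. `weighted_f1` averages per-class F1 with
#' weights equal to each class's share of the true labels; `macro_f1` is the
#' unweighted mean over classes present in `y_true`; `mcc_multiclass` is the
#' multiclass Matthews correlation coefficient computed from the confusion
#' matrix (0 when a denominator term vanishes).
#'
#' @inheritParams confusion_matrix
#' @return a single numeric value.
#' @export
weighted_f1 <- function(y_true, y_pred) {
  cm <- confusion_matrix(y_true, y_pred)
  f1 <- per_class_f1_from_confusion(cm)
  n_c <- rowSums(cm)
  present <- n_c > 0
  sum(n_c[present] / sum(n_c) * f1[present])
}

#' @rdname weighted_f1
#' @export
macro_f1 <- function(y_true, y_pred) {
  cm <- confusion_matrix(y_true, y_pred)
  f1 <- per_class_f1_from_confusion(cm)
  present <- rowSums(cm) > 0
  mean(f1[present])
}

#' @rdname weighted_f1
#' @export
accuracy <- function(y_true, y_pred) {
  cm <- confusion_matrix(y_true, y_pred)
  sum(diag(cm)) / sum(cm)
}

#' @rdname weighted_f1
#' @export
mcc_multiclass <- function(y_true, y_pred) {
  cm <- confusion_matrix(y_true, y_pred)
  mcc_from_confusion(cm)
}

mcc_from_confusion <- function(cm) {
  cm <- matrix(as.numeric(cm), nrow = nrow(cm))
  s <- sum(cm)
  c_ <- sum(diag(cm))
  tk <- rowSums(cm)   # true counts
  pk <- colSums(cm)   # predicted counts
  num <- c_ * s - sum(pk * tk)
  den <- sqrt(s^2 - sum(pk^2)) * sqrt(s^2 - sum(tk^2))
  if (den == 0) return(0)
  num / den
}

#' Evaluation report
#'
#' Bundles a confusion matrix with the four summary metrics and per-class F1.
#'
#' @param y_true,y_pred pooled true and predicted labels.
#' @param classes optional explicit class order.
#' @param meta optional named list recorded alongside (classifier, seeds, ...).
#' @return an object of class `evaluation_report` with fields `confusion`,
#'   `accuracy`, `mcc`, `macro_f1`, `weighted_f1`, `per_class_f1`, `meta`.
#' @export
evaluation_report <- function(y_true, y_pred, classes = NULL, meta = list()) {
  cm <- confusion_matrix(y_true, y_pred, classes = classes)
  f1 <- per_class_f1_from_confusion(cm)
  n_c <- rowSums(cm)
  present <- n_c > 0
  structure(
    list(confusion = cm,
         accuracy = sum(diag(cm)) / sum(cm),
         mcc = mcc_from_confusion(cm),
         macro_f1 = mean(f1[present]),
         weighted_f1 = sum(n_c[present] / sum(n_c) * f1[present]),
         per_class_f1 = f1,
         meta = meta),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "evaluation_report: n=%d  ACC=%.4f  MCC=%.4f  macro F1=%.4f  weighted F1=%.4f\n",
    sum(x$confusion), x$accuracy, x$mcc, x$macro_f1, x$weighted_f1))
  invisible(x)
}
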