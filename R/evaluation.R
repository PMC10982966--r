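#' Confusion matrix
#'
#' K x K integer matrix of counts with rows = true class and columns =
#' predicted class, in scheme label order.
#'
#' @param true_labels,predicted_labels Equal-length character vectors of
#'   scheme labels.
#' @param scheme A [class_scheme()].
#' @return Object of class `confusion_matrix` (an integer matrix with the
#'   scheme attached as an attribute).
#' @export
confusion_matrix <- function(true_labels, predicted_labels,
                             scheme = class_scheme()) {
  if (length(true_labels) != length(predicted_labels)) {
    stop("true and predicted label sequences differ in length")
  }
  assert_labels(true_labels, scheme, "true label")
  assert_labels(predicted_labels, scheme, "predicted label")
  cm <- table(factor(true_labels, levels = scheme$labels),
              factor(predicted_labels, levels = scheme$labels))
  m <- matrix(as.integer(cm), nrow = length(scheme$labels),
              dimnames = list(true = scheme$labels,
                              predicted = scheme$labels))
  structure(m, class = c("confusion_matrix", class(m)), scheme = scheme)
}

#' Balanced accuracy
#'
#' The macro-average of per-class recall: `mean_i counts[i,i] / rowsum[i]`
#' over classes with non-zero support. Classes with zero support are
#' excluded with a warning. Robust to class imbalance; with equal supports
#' it equals plain accuracy.
#'
#' @param cm A [confusion_matrix()].
#' @return Scalar in \[0, 1\].
#' @export
balanced_accuracy <- function(cm) {
  support <- rowSums(cm)
  if (all(support == 0)) stop("confusion matrix is all zero")
  if (any(support == 0)) {
    warning("zero-support class(es) excluded from balanced accuracy: ",
            paste(rownames(cm)[support == 0], collapse = ", "))
  }
  keep <- support > 0
  mean(diag(cm)[keep] / support[keep])
}

#' Macro-averaged precision, recall and F1
#'
#' Reduces the multiclass problem to one-vs-all binaries, computes
#' precision, recall and F1 per class, and averages with equal class
#' weights. A class that is never predicted contributes precision 0 (with a
#' warning), the conservative zero-division convention; a class with F1
#' denominator 0 contributes F1 0. Macro-F1 is the mean of per-class F1
#' values, not the F1 of the macro precision/recall pair. Zero-support
#' classes are excluded from all three averages.
#'
#' @param cm A [confusion_matrix()].
#' @return List with `per_class` (data frame: label, precision, recall, f1,
#'   support) and `macro` (named vector: precision, recall, f1).
#' @export
macro_metrics <- function(cm) {
  support <- rowSums(cm)
  predicted <- colSums(cm)
  if (all(support == 0)) stop("confusion matrix is all zero")
  tp <- diag(cm)
  never <- predicted == 0 & support > 0
  if (any(never)) {
    warning("never-predicted class(es) get precision 0: ",
            paste(rownames(cm)[never], collapse = ", "))
  }
  precision <- ifelse(predicted > 0, tp / predicted, 0)
  recall <- ifelse(support > 0, tp / support, NA_real_)
  f1 <- ifelse(precision + recall > 0 & !is.na(recall),
               2 * precision * recall / (precision + recall), 0)
  keep <- support > 0
  per_class <- data.frame(label = rownames(cm), precision = precision,
                          recall = recall, f1 = f1, support = support,
                          row.names = NULL)
  list(per_class = per_class,
       macro = c(precision = mean(precision[keep]),
                 recall = mean(recall[keep]),
                 f1 = mean(f1[keep])))
}

#' Collapse to binary tumor detection
#'
#' Collapses the K x K matrix onto the tumor / non-tumor partition of the
#' scheme and reports the two clinically relevant error rates: the false
#' alarm rate `P(predicted tumor | true non-tumor)` and the missed cancer
#' rate `P(predicted non-tumor | true tumor)`. Confusions between tumor
#' subtypes do not affect either rate.
#'
#' @param cm A [confusion_matrix()].
#' @param scheme A [class_scheme()]; defaults to the one attached to `cm`.
#' @return Named vector `c(false_alarm_rate, missed_cancer_rate)`.
#' @export
binary_collapse <- function(cm, scheme = attr(cm, "scheme")) {
  tumor <- rownames(cm) %in% scheme$tumor_labels
  if (!any(tumor) || all(tumor)) {
    stop("tumor/non-tumor partition has an empty side")
  }
  n_nontumor <- sum(cm[!tumor, , drop = FALSE])
  n_tumor <- sum(cm[tumor, , drop = FALSE])
  if (n_nontumor == 0 || n_tumor == 0) {
    stop("no support on one side of the tumor/non-tumor partition")
  }
  false_alarm <- sum(cm[!tumor, tumor, drop = FALSE]) / n_nontumor
  missed <- sum(cm[tumor, !tumor, drop = FALSE]) / n_tumor
  c(false_alarm_rate = false_alarm, missed_cancer_rate = missed)
}

#' Full metrics report
#'
#' Bundles the confusion matrix with per-class and macro-averaged metrics
#' and the binary tumor-detection collapse. Balanced accuracy and macro
#' recall are the same quantity under macro averaging and are reported under
#' both names.
#'
#' @param cm A [confusion_matrix()].
#' @return Object of class `metrics_report`: list with `confusion`,
#'   `per_class`, `macro` (balanced_accuracy, precision, recall, f1) and
#'   `binary`.
#' @export
metrics_report <- function(cm) {
  mm <- suppressWarnings(macro_metrics(cm))
  bacc <- suppressWarnings(balanced_accuracy(cm))
  structure(
    list(confusion = cm, per_class = mm$per_class,
         macro = c(balanced_accuracy = bacc, mm$macro),
         binary = binary_collapse(cm)),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  print(round(x$macro, 4))
  cat("binary tumor detection: false alarm ",
      round(x$binary["false_alarm_rate"], 4), ", missed cancer ",
      round(x$binary["missed_cancer_rate"], 4), "\n", sep = "")
  invisible(x)
}

#' Serialize a metrics report
#'
#' Writes the report as JSON and, optionally, the confusion matrix as a
#' labeled TSV.
#'
#' @param report A [metrics_report()].
#' @param path JSON output path.
#' @param confusion_tsv Optional TSV path for the confusion matrix.
#' @export
write_metrics_report <- function(report, path, confusion_tsv = NULL) {
  out <- list(
    macro = as.list(report$macro),
    per_class = report$per_class,
    binary = as.list(report$binary),
    confusion = list(labels = rownames(report$confusion),
                     counts = unclass(report$confusion))
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(confusion_tsv)) {
    utils::write.table(
      cbind(true = rownames(report$confusion), as.data.frame(
        unclass(report$confusion))),
      confusion_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
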