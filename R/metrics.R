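# Confusion-count assembly and the six-statistic evaluation suite:
# accuracy, recall, precision, F-measure, specificity, G-means.

#' Confusion counts from label vectors
#'
#' One-vs-rest binarization against `positive_class`: a sample is positive
#' when its label equals `positive_class`, negative otherwise.
#'
#' @param true_labels,predicted_labels equal-length non-empty vectors.
#' @param positive_class the label treated as positive.
#' @return object of class `confusion_counts` with integer `TP`, `TN`,
#'   `FP`, `FN`.
#' @export
confusion_from_predictions <- function(true_labels, predicted_labels,
                                       positive_class) {
  if (length(true_labels) == 0) data_stop("empty label vectors")
  if (length(true_labels) != length(predicted_labels)) {
    data_stop("true and predicted label vectors differ in length")
  }
  tp_true <- true_labels == positive_class
  tp_pred <- predicted_labels == positive_class
  confusion_counts(TP = sum(tp_true & tp_pred),
                   TN = sum(!tp_true & !tp_pred),
                   FP = sum(!tp_true & tp_pred),
                   FN = sum(tp_true & !tp_pred))
}

#' Construct confusion counts directly
#'
#' @param TP,TN,FP,FN non-negative integer counts (total `>= 1`).
#' @return object of class `confusion_counts`.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  counts <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(counts < 0)) data_stop("confusion counts must be non-negative")
  structure(as.list(as.integer(counts)) |> stats::setNames(names(counts)),
            class = "confusion_counts")
}

safe_ratio <- function(num, den) if (den > 0) num / den else NA_real_

#' The six-statistic metrics report
#'
#' From confusion counts: accuracy `(TP+TN)/total`, recall `TP/(TP+FN)`,
#' precision `TP/(TP+FP)`, F-measure (harmonic mean of recall and
#' precision), specificity `TN/(TN+FP)`, and G-means, by default the
#' geometric mean `sqrt(recall * specificity)`. Ratios with a zero
#' denominator are reported as `NA` (missing), never as 0.
#'
#' The F-measure as sometimes typeset with the product `recall * precision`
#' in the denominator is degenerate (it always equals 2); this
#' implementation uses the standard harmonic-mean form. Likewise, G-means
#' written as a bare product `recall * specificity` is available behind
#' `g_means_as_printed = TRUE`, but the conventional geometric mean is the
#' default.
#'
#' @param counts a [confusion_counts()] object.
#' @param g_means_as_printed compute G-means as the bare product instead of
#'   its square root.
#' @return object of class `metrics_report`: named list of the six
#'   statistics, each in `[0,1]` or `NA`.
#' @export
compute_metrics <- function(counts, g_means_as_printed = FALSE) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$TP + counts$TN + counts$FP + counts$FN
  if (total < 1) data_stop("metrics require at least one counted sample")
  recall <- safe_ratio(counts$TP, counts$TP + counts$FN)
  precision <- safe_ratio(counts$TP, counts$TP + counts$FP)
  specificity <- safe_ratio(counts$TN, counts$TN + counts$FP)
  f_measure <- if (is.na(recall) || is.na(precision) ||
                   recall + precision == 0) {
    NA_real_
  } else {
    2 * recall * precision / (recall + precision)
  }
  g_means <- if (is.na(recall) || is.na(specificity)) {
    NA_real_
  } else if (g_means_as_printed) {
    recall * specificity
  } else {
    sqrt(recall * specificity)
  }
  structure(list(accuracy = (counts$TP + counts$TN) / total,
                 recall = recall, precision = precision,
                 f_measure = f_measure, specificity = specificity,
                 g_means = g_means),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(format_metrics_table(list(overall = x)))
  invisible(x)
}

#' Per-class and macro-averaged metrics for multiclass labels
#'
#' One-vs-rest counts per class plus the macro average (mean of each
#' statistic over classes, `NA`s removed).
#'
#' @param true_labels,predicted_labels equal-length label vectors.
#' @param classes class labels to report; defaults to those present in
#'   `true_labels`.
#' @param g_means_as_printed passed to [compute_metrics()].
#' @return list with `per_class` (named list of `metrics_report`) and
#'   `macro` (named numeric vector).
#' @export
metrics_macro <- function(true_labels, predicted_labels, classes = NULL,
                          g_means_as_printed = FALSE) {
  classes <- classes %||% sort(unique(true_labels))
  per_class <- lapply(classes, function(cl) {
    compute_metrics(
      confusion_from_predictions(true_labels, predicted_labels, cl),
      g_means_as_printed)
  })
  names(per_class) <- as.character(classes)
  stats_names <- names(per_class[[1]])
  macro <- vapply(stats_names, function(s) {
    mean(vapply(per_class, function(m) m[[s]], numeric(1)), na.rm = TRUE)
  }, numeric(1))
  list(per_class = per_class, macro = macro)
}

#' Format metric reports as an aligned plain-text table
#'
#' @param reports named list of `metrics_report` objects (or numeric
#'   vectors), one row each.
#' @return a single character string.
#' @export
format_metrics_table <- function(reports) {
  stats_names <- c("accuracy", "recall", "precision", "f_measure",
                   "specificity", "g_means")
  header <- sprintf("%-12s %s", "class",
                    paste(sprintf("%11s", stats_names), collapse = " "))
  rows <- vapply(names(reports), function(nm) {
    vals <- vapply(stats_names, function(s) {
      v <- reports[[nm]][[s]]
      if (is.null(v) || is.na(v)) "NA" else sprintf("%.6f", v)
    }, character(1))
    sprintf("%-12s %s", nm, paste(sprintf("%11s", vals), collapse = " "))
  }, character(1))
  paste0(paste(c(header, rows), collapse = "\n"), "\n")
}
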