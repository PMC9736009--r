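#' Confusion matrix from a prediction set
#'
#' Cell `(i, j)` counts samples whose true class is `i` and predicted class
#' is `j`, in a fixed, recorded class order.
#'
#' @param predictions A `prediction_set`, or anything with `true_label` and
#'   `predicted_label` columns.
#' @param class_order Character vector fixing the class order; defaults to
#'   the sorted union of observed labels. All labels must be present in it.
#' @return Square integer matrix of class `confusion_matrix` with dimnames
#'   `true` x `predicted`.
#' @export
confusion_matrix <- function(predictions, class_order = NULL) {
  truth <- as.character(predictions$true_label)
  pred <- as.character(predictions$predicted_label)
  if (is.null(class_order)) class_order <- sort(unique(c(truth, pred)))
  unknown <- setdiff(unique(c(truth, pred)), class_order)
  if (length(unknown) > 0) {
    stop(sprintf("labels not in class_order: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  cm <- table(factor(truth, levels = class_order),
              factor(pred, levels = class_order))
  cm <- matrix(as.integer(cm), nrow = length(class_order),
               dimnames = list(true = class_order, predicted = class_order))
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' One-vs-rest counts for a class
#'
#' Reduces the multiclass confusion matrix to the binary counts for class
#' `cl`: TP is the diagonal cell, FP the rest of its predicted column, FN
#' the rest of its true row, TN everything else.
#'
#' @param cm A `confusion_matrix`.
#' @param cl Class name.
#' @return Named numeric vector `c(TP, FP, FN, TN)`.
#' @export
one_vs_rest_counts <- function(cm, cl) {
  classes <- rownames(cm)
  if (!cl %in% classes) stop(sprintf("class '%s' not in matrix", cl), call. = FALSE)
  tp <- cm[cl, cl]
  fp <- sum(cm[, cl]) - tp
  fn <- sum(cm[cl, ]) - tp
  tn <- sum(cm) - tp - fp - fn
  c(TP = tp, FP = fp, FN = fn, TN = tn)
}

#' Per-class precision, recall and specificity (percent)
#'
#' `precision = 100 TP / (TP + FP)`, `recall = 100 TP / (TP + FN)`,
#' `specificity = 100 TN / (TN + FP)`. A zero denominator yields 0 with
#' a `degenerate` flag rather than an error, so empty predicted classes
#' don't abort a report.
#'
#' @param counts Named vector from [one_vs_rest_counts()].
#' @return Named list: `precision`, `recall`, `specificity` (percent) and
#'   `degenerate` (logical).
#' @export
class_metrics <- function(counts) {
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  safe <- function(num, den) if (den > 0) 100 * num / den else 0
  list(
    precision = safe(counts[["TP"]], counts[["TP"]] + counts[["FP"]]),
    recall = safe(counts[["TP"]], counts[["TP"]] + counts[["FN"]]),
    specificity = safe(counts[["TN"]], counts[["TN"]] + counts[["FP"]]),
    degenerate = (counts[["TP"]] + counts[["FP"]] == 0) ||
      (counts[["TP"]] + counts[["FN"]] == 0) ||
      (counts[["TN"]] + counts[["FP"]] == 0)
  )
}

#' F1 score from precision and recall (percent)
#'
#' Harmonic mean `2 P Re / (P + Re)`; 0 when both are 0.
#'
#' @param precision,recall Percent values in `[0, 100]`.
#' @return F1 in percent.
#' @export
f1_score <- function(precision, recall) {
  stopifnot(precision >= 0, precision <= 100, recall >= 0, recall <= 100)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Overall accuracy of a confusion matrix (percent)
#'
#' The rate of correct predictions over all predictions:
#' `100 * trace(cm) / total`.
#'
#' @param cm A `confusion_matrix`.
#' @return Accuracy in percent.
#' @export
overall_accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  100 * sum(diag(cm)) / total
}

#' Macro (unweighted) average of a per-class metric
#'
#' Arithmetic mean over classes; when `report = TRUE` the value is rounded
#' to 1 decimal place, half away from zero — the report convention.
#'
#' @param values Per-class metric values (percent).
#' @param report Round for reporting (default TRUE).
#' @return Mean value in percent.
#' @export
macro_average <- function(values, report = TRUE) {
  if (length(values) < 1) stop("need at least one class", call. = FALSE)
  m <- mean(values)
  if (report) round_half_away(m, 1) else m
}

#' Full metrics table for a prediction set
#'
#' Per class: precision, recall, specificity and F1 (percent); plus the
#' macro average of each and the overall accuracy — the layout of a
#' per-combination cross-validation report.
#'
#' @param predictions A `prediction_set` (or a `confusion_matrix`).
#' @param class_order Optional fixed class order.
#' @param digits Report rounding (1 dp, half away from zero); `NULL` for
#'   unrounded values.
#' @return Object of class `metrics_table`: a `data.frame` with one row per
#'   class plus an `Average` row, columns `class`, `precision`, `recall`,
#'   `specificity`, `f1`, and the overall accuracy as attribute `accuracy`.
#' @export
metrics_table <- function(predictions, class_order = NULL, digits = 1) {
  cm <- if (inherits(predictions, "confusion_matrix")) predictions
        else confusion_matrix(predictions, class_order)
  classes <- rownames(cm)
  rows <- lapply(classes, function(cl) {
    m <- class_metrics(one_vs_rest_counts(cm, cl))
    data.frame(class = cl, precision = m$precision, recall = m$recall,
               specificity = m$specificity,
               f1 = f1_score(m$precision, m$recall))
  })
  tab <- do.call(rbind, rows)
  avg <- data.frame(class = "Average",
                    precision = mean(tab$precision),
                    recall = mean(tab$recall),
                    specificity = mean(tab$specificity),
                    f1 = mean(tab$f1))
  out <- rbind(tab, avg)
  acc <- overall_accuracy(cm)
  if (!is.null(digits)) {
    num <- c("precision", "recall", "specificity", "f1")
    out[num] <- lapply(out[num], round_half_away, digits = digits)
    acc <- round_half_away(acc, digits)
  }
  structure(out, class = c("metrics_table", "data.frame"),
            accuracy = acc, confusion = cm)
}

#' @export
print.metrics_table <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  cat(sprintf("Overall accuracy: %s%%\n", attr(x, "accuracy")))
  invisible(x)
}

#' Write a metrics table (CSV + JSON) and its confusion matrix (CSV)
#'
#' @param table A `metrics_table`.
#' @param path CSV path; `<path>.json` mirrors it with the accuracy, and
#'   `<path>.confusion.csv` holds the confusion matrix.
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(table, path) {
  stopifnot(inherits(table, "metrics_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(per_class = as.data.frame(table), accuracy = attr(table, "accuracy")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  cm <- attr(table, "confusion")
  if (!is.null(cm)) {
    utils::write.csv(as.data.frame(unclass(cm)), paste0(path, ".confusion.csv"),
                     quote = FALSE)
  }
  invisible(path)
}
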