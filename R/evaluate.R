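#' Classification metrics from predictions and truth
#'
#' Builds the confusion matrix over the class universe and computes overall
#' accuracy (fraction correct) plus per-class one-vs-rest true/false
#' positive/negative counts, precision `Tp / (Tp + Fp)`, recall
#' `Tp / (Tp + Fn)` and F1 `2 P R / (P + R)`; macro averages over classes.
#' Undefined ratios (empty denominator) are reported as 0.
#'
#' @param predicted,truth equal-length label vectors drawn from `classes`.
#' @param classes ordered class universe (default grades 0--4).
#' @return an object of class `dr_eval_report`: `confusion` (truth rows,
#'   predicted columns), `accuracy`, `per_class` data frame (Tp, Tn, Fp,
#'   Fn, precision, recall, f1), `macro_precision`, `macro_recall`,
#'   `macro_f1`.
#' @export
evaluate_predictions <- function(predicted, truth, classes = 0:4) {
  if (length(predicted) != length(truth)) stop("length mismatch")
  if (!all(predicted %in% classes) || !all(truth %in% classes))
    stop("labels outside the class universe")
  cm <- table(factor(truth, levels = classes),
              factor(predicted, levels = classes))
  cm <- matrix(as.integer(cm), nrow = length(classes),
               dimnames = list(truth = classes, predicted = classes))
  n <- sum(cm)
  accuracy <- sum(diag(cm)) / n
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  per <- lapply(seq_along(classes), function(i) {
    tp <- cm[i, i]
    fp <- sum(cm[-i, i])
    fn <- sum(cm[i, -i])
    tn <- n - tp - fp - fn
    pr <- safe_div(tp, tp + fp)
    re <- safe_div(tp, tp + fn)
    f1 <- safe_div(2 * pr * re, pr + re)
    data.frame(class = classes[i], Tp = tp, Tn = tn, Fp = fp, Fn = fn,
               precision = pr, recall = re, f1 = f1)
  })
  per <- do.call(rbind, per)
  structure(list(confusion = cm, accuracy = accuracy, per_class = per,
                 macro_precision = mean(per$precision),
                 macro_recall = mean(per$recall),
                 macro_f1 = mean(per$f1)),
            class = "dr_eval_report")
}

#' @export
print.dr_eval_report <- function(x, ...) {
  cat(sprintf(
    "<dr_eval_report> accuracy %.4f | macro P %.4f R %.4f F1 %.4f\n",
    x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1))
  print(x$confusion)
  invisible(x)
}

#' Serialize an evaluation report
#'
#' Writes the report as JSON and, optionally, the confusion matrix as CSV.
#'
#' @param report a `dr_eval_report`.
#' @param path JSON output path.
#' @param confusion_csv optional CSV path for the confusion matrix.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path, confusion_csv = NULL) {
  jsonlite::write_json(
    list(accuracy = report$accuracy,
         macro_precision = report$macro_precision,
         macro_recall = report$macro_recall,
         macro_f1 = report$macro_f1,
         per_class = report$per_class,
         confusion = unname(as.data.frame(report$confusion))),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(confusion_csv)) {
    utils::write.csv(as.data.frame(report$confusion), confusion_csv)
  }
  invisible(path)
}
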