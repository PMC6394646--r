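# Evaluation: confusion matrix, per-class precision / recall / F1
# (harmonic mean of precision and recall), macro averages and overall
# accuracy.

#' Evaluate predicted against gold labels
#'
#' Per class: `P = TP/(TP+FP)`, `R = TP/(TP+FN)`,
#' `F1 = 2PR/(P+R)`; `F1 = 0` by convention when `P + R = 0`.  A class
#' absent from both predictions and gold has undefined P and R, reported
#' as 0 and flagged in the `undefined` column.  Macro averages are
#' unweighted means over classes; overall accuracy is the sample-weighted
#' (micro) accuracy, `trace(confusion) / n`.
#'
#' @param predictions,gold Aligned label vectors.
#' @param frame Frame of discernment (fixes class order in the matrix).
#' @return An `eval_report`: list with `confusion` (rows = truth, columns
#'   = prediction), `per_class` tibble (`tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`, `undefined`), `macro_f1`, `macro_precision`,
#'   `macro_recall`, `accuracy`, `n`.
#' @export
#' @examples
#' f <- adl_frame(c("a", "b"))
#' evaluate_predictions(c("a", "a", "b"), c("a", "b", "b"), f)
evaluate_predictions <- function(predictions, gold, frame = adl_frame()) {
  frame <- as_frame(frame)
  if (length(predictions) != length(gold)) {
    stop("predictions and gold labels differ in length", call. = FALSE)
  }
  labs <- as.character(frame)
  if (any(!predictions %in% labs) || any(!gold %in% labs)) {
    stop("labels outside the frame", call. = FALSE)
  }
  conf <- table(factor(gold, levels = labs),
                factor(predictions, levels = labs))
  tp <- diag(conf)
  fp <- colSums(conf) - tp
  fn <- rowSums(conf) - tp
  undefined <- (tp + fp + fn) == 0
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  per_class <- tibble::tibble(
    activity = labs, tp = as.integer(tp), fp = as.integer(fp),
    fn = as.integer(fn), precision = unname(precision),
    recall = unname(recall), f1 = unname(f1),
    undefined = unname(undefined))
  structure(list(
    confusion = unclass(conf),
    per_class = per_class,
    macro_precision = mean(precision),
    macro_recall = mean(recall),
    macro_f1 = mean(f1),
    accuracy = sum(tp) / length(gold),
    n = length(gold)
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 3, ...) {
  cat("<eval_report: n = ", x$n, ", accuracy = ",
      round(x$accuracy, digits), ", macro-F1 = ",
      round(x$macro_f1, digits), ">\n", sep = "")
  print(x$per_class, n = nrow(x$per_class))
  invisible(x)
}
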