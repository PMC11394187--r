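# Evaluation statistics: 2x2 confusion matrices and accuracy.

#' Cross-tabulate predictions against truth
#'
#' Labels are binarized by `positive_label`: everything else counts as
#' negative. Orientation: `tp` = predicted positive & truly positive.
#'
#' @param pred,truth Equal-length label vectors.
#' @param positive_label The label treated as positive.
#' @return A `confusion_2x2`: list with `tp`, `fn`, `fp`, `tn`.
#' @export
confusion <- function(pred, truth, positive_label) {
  if (length(pred) != length(truth))
    stop("pred and truth differ in length (", length(pred), " vs ",
         length(truth), ")")
  if (length(pred) == 0) stop("empty label vectors")
  p <- pred == positive_label
  t <- truth == positive_label
  structure(list(tp = sum(p & t), fn = sum(!p & t),
                 fp = sum(p & !t), tn = sum(!p & !t)),
            class = "confusion_2x2")
}

#' Build a confusion matrix directly from counts
#'
#' @param tp,fn,fp,tn Non-negative integer counts.
#' @return A `confusion_2x2`.
#' @export
confusion_counts <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  structure(as.list(counts), class = "confusion_2x2")
}

#' @export
print.confusion_2x2 <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(c("pred +", "pred -"), c("true +", "true -")))
  print(m)
  cat(sprintf("accuracy: %.1f%%\n", accuracy(x)))
  invisible(x)
}

#' Accuracy of a 2x2 confusion matrix
#'
#' `100 * (tp + tn) / total`, reported to one decimal place (round half up).
#'
#' @param cm A `confusion_2x2`.
#' @return Percentage in [0, 100].
#' @export
accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_2x2"))
  total <- cm$tp + cm$fn + cm$fp + cm$tn
  if (total <= 0) stop("confusion matrix total must be positive")
  round_half_up(100 * (cm$tp + cm$tn) / total, 1)
}

round_half_up <- function(x, digits) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Evaluate a prediction table against a truth table
#'
#' @param pred_df,truth_df Data frames with columns `case_id` and `label`;
#'   joined on `case_id`.
#' @param positive_label The positive class.
#' @return List with the four counts and `accuracy`.
#' @export
evaluate_predictions <- function(pred_df, truth_df, positive_label) {
  need <- c("case_id", "label")
  if (!all(need %in% names(pred_df)) || !all(need %in% names(truth_df)))
    stop("prediction and truth tables need columns case_id, label")
  merged <- merge(pred_df, truth_df, by = "case_id",
                  suffixes = c("_pred", "_truth"))
  if (nrow(merged) == 0) stop("no case_id overlap between tables")
  cm <- confusion(merged$label_pred, merged$label_truth, positive_label)
  list(tp = cm$tp, fn = cm$fn, fp = cm$fp, tn = cm$tn, accuracy = accuracy(cm))
}

#' Published validation tables shipped with the package
#'
#' Row-level expansions of the two printed 2x2 validation tables: the
#' 186-site residual-stone versus encrustation task and the 222-case
#' positive/negative judgment task.
#'
#' @param which `"stone_sites"` or `"case_judgment"`.
#' @return Data frame with `case_id`, `pred`, `truth`.
#' @export
paper_validation_table <- function(which = c("stone_sites", "case_judgment")) {
  which <- match.arg(which)
  file <- system.file("extdata",
                      paste0(which, ".csv"), package = "stentcheck")
  if (file == "") stop("packaged table not found; is stentcheck installed?")
  utils::read.csv(file, stringsAsFactors = FALSE)
}
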