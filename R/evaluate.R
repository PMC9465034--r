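#' Confusion matrix
#'
#' @param y_true,y_pred integer labels (0-based), equal length, all below
#'   `n_classes`.
#' @param n_classes number of classes.
#' @return An `n_classes x n_classes` count matrix; entry `(i, j)` is the
#'   number of true-class-`i` items predicted as class `j` (0-based classes
#'   on dimnames).
#' @export
confusion <- function(y_true, y_pred, n_classes) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) &&
      (min(y_true, y_pred) < 0 || max(y_true, y_pred) >= n_classes))
    stop("label out of range")
  lev <- 0:(n_classes - 1)
  m <- table(factor(y_true, levels = lev), factor(y_pred, levels = lev))
  matrix(m, n_classes, n_classes, dimnames = list(true = lev, pred = lev))
}

#' Per-class precision, recall, F1 and overall accuracy
#'
#' Precision of class i is the fraction of items predicted i that are truly
#' i, recall the fraction of truly-i items predicted i, and the F1-score
#' their harmonic mean `2 P R / (P + R)`; accuracy is the fraction of all
#' predictions that are correct (matrix trace over total). A class with zero
#' support (or never predicted) has its recall (or precision) reported as
#' `NA` and flagged in `undefined`, rather than silently set to 0.
#'
#' @param m square confusion-count matrix from [confusion()].
#' @return A list of class `eval_report`: `confusion`, `precision`, `recall`,
#'   `f1`, `accuracy`, `undefined` (character vector naming any undefined
#'   per-class metrics).
#' @export
eval_metrics <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m) || nrow(m) == 0) stop("confusion matrix must be square")
  tp <- diag(m)
  pred_tot <- colSums(m)
  true_tot <- rowSums(m)
  precision <- ifelse(pred_tot > 0, tp / pred_tot, NA_real_)
  recall <- ifelse(true_tot > 0, tp / true_tot, NA_real_)
  f1 <- ifelse(!is.na(precision) & !is.na(recall) & (precision + recall) > 0,
               2 * precision * recall / (precision + recall),
               ifelse(!is.na(precision) & !is.na(recall), 0, NA_real_))
  undefined <- c(
    if (any(is.na(precision))) paste0("precision_", which(is.na(precision)) - 1),
    if (any(is.na(recall))) paste0("recall_", which(is.na(recall)) - 1))
  structure(list(confusion = m, precision = precision, recall = recall,
                 f1 = f1, accuracy = sum(tp) / sum(m),
                 undefined = undefined),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> accuracy %.3f\n", x$accuracy))
  tab <- data.frame(precision = round(x$precision, 3),
                    recall = round(x$recall, 3), f1 = round(x$f1, 3))
  rownames(tab) <- paste0("class_", seq_len(nrow(tab)) - 1)
  print(tab)
  if (length(x$undefined))
    cat("undefined:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate predictions directly
#' @inheritParams confusion
#' @return An `eval_report` (see [eval_metrics()]).
#' @export
evaluate_predictions <- function(y_true, y_pred, n_classes) {
  eval_metrics(confusion(y_true, y_pred, n_classes))
}

#' Write an evaluation report as JSON and CSV
#' @param report an `eval_report`; @param path_json,path_csv output paths
#'   (either may be NULL to skip).
#' @return `report`, invisibly.
#' @export
write_eval_report <- function(report, path_json = NULL, path_csv = NULL) {
  if (!is.null(path_json))
    jsonlite::write_json(list(confusion = report$confusion,
                              precision = report$precision,
                              recall = report$recall, f1 = report$f1,
                              accuracy = report$accuracy,
                              undefined = report$undefined),
                         path_json, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, na = "null")
  if (!is.null(path_csv)) {
    tab <- data.frame(class = seq_along(report$precision) - 1,
                      precision = report$precision, recall = report$recall,
                      f1 = report$f1)
    utils::write.csv(tab, path_csv, row.names = FALSE)
  }
  invisible(report)
}
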