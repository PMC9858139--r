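#' Confusion counts from predicted and true labels or masks
#'
#' Tallies the 2x2 confusion table. Inputs may be label vectors/factors
#' (positive class `"abnormal"` by convention) or [binary_mask()] /
#' 0-1 matrices (positive = 1, i.e. tumor).
#'
#' @param pred Predicted labels or mask.
#' @param truth Ground-truth labels or mask (same length/shape).
#' @param positive The positive label for vector input.
#' @return An object of class `confusion_counts`: `TP`, `FP`, `TN`, `FN`.
#' @export
#' @examples
#' confusion_counts(c("abnormal", "normal"), c("abnormal", "abnormal"))
confusion_counts <- function(pred, truth, positive = "abnormal") {
  tobin <- function(x) {
    if (inherits(x, "binary_mask")) return(as.vector(x$pixels) == 1)
    if (is.matrix(x)) return(as.vector(x) == 1)
    as.character(x) == positive
  }
  p <- tobin(pred); t <- tobin(truth)
  if (length(p) != length(t))
    stop("confusion_counts: pred and truth differ in length/shape")
  structure(list(TP = sum(p & t), FP = sum(p & !t),
                 TN = sum(!p & !t), FN = sum(!p & t)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP=%d FP=%d TN=%d FN=%d\n", x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Classification metrics on the percent scale
#'
#' Computes accuracy, TPR (sensitivity), TNR (specificity), PPV
#' (precision), F-score (harmonic mean of PPV and TPR), and the balanced
#' AUC `(TPR + TNR) / 2`, all as percentages. A metric whose denominator
#' is zero is reported as `NA` (an explicit undefined marker, never a
#' silent 0); the report is still emitted.
#'
#' @param c A [confusion_counts()].
#' @return An object of class `metrics_report` (also a list):
#'   `accuracy`, `tpr`, `tnr`, `ppv`, `f_score`, `auc`, each in
#'   `[0, 100]` or `NA`.
#' @export
#' @examples
#' classification_metrics(structure(list(TP = 3, FP = 1, TN = 5, FN = 1),
#'                        class = "confusion_counts"))
classification_metrics <- function(c) {
  rate <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  tpr <- rate(c$TP, c$TP + c$FN)
  tnr <- rate(c$TN, c$TN + c$FP)
  ppv <- rate(c$TP, c$TP + c$FP)
  f <- if (!is.na(tpr) && !is.na(ppv) && (tpr + ppv) > 0)
    2 * ppv * tpr / (ppv + tpr) else NA_real_
  acc <- rate(c$TP + c$TN, c$TP + c$TN + c$FP + c$FN)
  auc <- if (!is.na(tpr) && !is.na(tnr)) (tpr + tnr) / 2 else NA_real_
  structure(list(accuracy = acc, tpr = tpr, tnr = tnr, ppv = ppv,
                 f_score = f, auc = auc),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  v <- unlist(unclass(x))
  cat(paste(sprintf("%s=%.2f", names(v), v), collapse = " "), "\n")
  invisible(x)
}

#' Dice similarity coefficient
#'
#' `2 |S intersect SG| / (|S| + |SG|)` on the `[0, 1]` scale (multiply
#' by 100 for report tables). Symmetric; equals 1 for identical
#' non-empty masks and `NA` when both masks are empty.
#'
#' @param S,SG [binary_mask()] objects or 0-1 matrices of equal shape.
#' @return DSC in `[0, 1]`, or `NA` for two empty masks.
#' @export
#' @examples
#' a <- matrix(c(1, 1, 0, 0), 2); b <- matrix(c(1, 0, 1, 0), 2)
#' dice_coefficient(a, b)
dice_coefficient <- function(S, SG) {
  s <- if (inherits(S, "binary_mask")) S$pixels else as.matrix(S)
  g <- if (inherits(SG, "binary_mask")) SG$pixels else as.matrix(SG)
  if (!all(dim(s) == dim(g)))
    stop("dice_coefficient: masks differ in shape")
  tot <- sum(s) + sum(g)
  if (tot == 0) return(NA_real_)
  2 * sum(s * g) / tot
}

#' Mean and standard deviation across fold reports
#'
#' Arithmetic mean and sample standard deviation (n - 1) of each metric
#' across folds, on the percent scale. Undefined (`NA`) entries are
#' excluded from the mean with a message noting how many were dropped.
#'
#' @param reports List of `metrics_report` objects (or a data frame of
#'   per-fold metric columns).
#' @return Data frame with rows `mean` and `sd`, one column per metric.
#' @export
#' @examples
#' summarize_folds(data.frame(accuracy = c(100, 100, 98.5, 100, 99.4)))
summarize_folds <- function(reports) {
  df <- if (is.data.frame(reports)) reports else
    do.call(rbind, lapply(reports, function(r) as.data.frame(unclass(r))))
  df <- df[, setdiff(names(df), "fold"), drop = FALSE]
  nas <- sum(is.na(df))
  if (nas > 0)
    message("summarize_folds: ", nas,
            " undefined metric value(s) excluded from the summary")
  out <- rbind(mean = vapply(df, mean, 0, na.rm = TRUE),
               sd = vapply(df, sd, 0, na.rm = TRUE))
  as.data.frame(out)
}
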