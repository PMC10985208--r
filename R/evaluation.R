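#' Confusion-matrix counts for binary miRNA classification
#'
#' A true positive is a sample labelled miRNA and predicted miRNA; a
#' false positive is predicted miRNA but not labelled miRNA; true/false
#' negatives analogously. The four counts partition the samples.
#'
#' @param labels,predictions vectors of 0/1 (1 = miRNA) of equal length.
#' @return named integer vector c(TP, FP, TN, FN).
#' @export
confusion <- function(labels, predictions) {
  if (length(labels) != length(predictions))
    stop("labels and predictions must have equal length")
  labels <- as.integer(labels); predictions <- as.integer(predictions)
  c(TP = sum(labels == 1L & predictions == 1L),
    FP = sum(labels == 0L & predictions == 1L),
    TN = sum(labels == 0L & predictions == 0L),
    FN = sum(labels == 1L & predictions == 0L))
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' Computes
#' accuracy = (TP+TN)/(TP+FP+FN+TN), precision = TP/(TP+FP),
#' recall = TP/(TP+FN) and F1 = 2*TP/(2*TP+FP+FN). A metric whose
#' denominator vanishes is reported as `NaN` with a warning, never as a
#' silent zero.
#'
#' @param TP,FP,TN,FN non-negative counts; alternatively pass the named
#'   vector from [confusion()] as `TP`.
#' @return an object of class `metrics_report`: the four counts and the
#'   four metrics.
#' @export
classification_metrics <- function(TP, FP = NULL, TN = NULL, FN = NULL) {
  if (is.null(FP) && length(TP) == 4) {
    cm <- TP; TP <- cm[["TP"]]; FP <- cm[["FP"]]
    TN <- cm[["TN"]]; FN <- cm[["FN"]]
  }
  stopifnot(TP >= 0, FP >= 0, TN >= 0, FN >= 0)
  total <- TP + FP + TN + FN
  if (total == 0) stop("all confusion counts are zero")
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reported as NaN",
              call. = FALSE)
      return(NaN)
    }
    num / den
  }
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN,
                 accuracy = (TP + TN) / total,
                 precision = ratio(TP, TP + FP, "precision"),
                 recall = ratio(TP, TP + FN, "recall"),
                 f1 = ratio(2 * TP, 2 * TP + FP + FN, "F1")),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat("TP ", x$TP, "  FP ", x$FP, "  TN ", x$TN, "  FN ", x$FN, "\n",
      "accuracy ", round(x$accuracy, digits),
      "  precision ", round(x$precision, digits),
      "  recall ", round(x$recall, digits),
      "  F1 ", round(x$f1, digits), "\n", sep = "")
  invisible(x)
}
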