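# Evaluation metrics for the four-class BI-RADS problem: the 4x4 confusion
# matrix (rows = actual, columns = predicted, order B-2..B-5), overall
# accuracy, one-vs-rest sensitivity/specificity per class, and micro-averaged
# PPV / NPV / MCC obtained by pooling the one-vs-rest TP/FP/FN/TN counts
# across classes before applying the metric formulas.

#' Confusion matrix over the four BI-RADS classes
#'
#' @param actual,predicted equal-length label vectors over
#'   `B2, B3, B4, B5`.
#' @param classes class order (default `B2 B3 B4 B5`).
#' @return 4x4 integer matrix, rows = actual, columns = predicted.
#' @export
confusionMatrix <- function(actual, predicted, classes = .BIRADS_CLASSES) {
  actual <- as.character(actual); predicted <- as.character(predicted)
  if (length(actual) != length(predicted)) stop("label length mismatch")
  if (!all(c(actual, predicted) %in% classes))
    stop("unknown label; expected one of ", paste(classes, collapse = ", "))
  cm <- table(factor(actual, levels = classes),
              factor(predicted, levels = classes))
  m <- matrix(as.integer(cm), length(classes), length(classes),
              dimnames = list(actual = classes, predicted = classes))
  m
}

#' Overall classification accuracy
#'
#' Correct predictions (the matrix trace) divided by the total number of
#' evaluated cases.
#'
#' @param cm confusion matrix (actual x predicted).
#' @return fraction in `[0, 1]`.
#' @export
accuracyFromCM <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  sum(diag(cm)) / total
}

# one-vs-rest counts per class: TP, FP, FN, TN
.ovrCounts <- function(cm) {
  total <- sum(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- total - tp - fp - fn
  cbind(TP = tp, FP = fp, FN = fn, TN = tn)
}

#' Per-class sensitivity and specificity
#'
#' One-vs-rest rates per class: sensitivity `TP / (TP + FN)`, specificity
#' `TN / (TN + FP)`. A class with no actual cases reports `NA` sensitivity.
#'
#' @param cm confusion matrix.
#' @return data.frame with columns `class`, `sensitivity`, `specificity`,
#'   `TP`, `FP`, `FN`, `TN`.
#' @export
perClassRates <- function(cm) {
  counts <- .ovrCounts(cm)
  sens <- ifelse(counts[, "TP"] + counts[, "FN"] > 0,
                 counts[, "TP"] / (counts[, "TP"] + counts[, "FN"]), NA_real_)
  spec <- ifelse(counts[, "TN"] + counts[, "FP"] > 0,
                 counts[, "TN"] / (counts[, "TN"] + counts[, "FP"]), NA_real_)
  cls <- rownames(cm)
  if (is.null(cls)) cls <- .BIRADS_CLASSES[seq_len(nrow(cm))]
  data.frame(class = cls, sensitivity = unname(sens),
             specificity = unname(spec), counts, row.names = NULL)
}

#' Micro-averaged PPV, NPV and MCC
#'
#' The one-vs-rest TP/FP/FN/TN counts are summed across the four classes and
#' the metric formulas applied to the pooled counts:
#' `PPV = TP/(TP+FP)`, `NPV = TN/(TN+FN)`,
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))` (0 by
#' convention when a factor of the denominator vanishes). For a single-label
#' multi-class matrix the pooled FP and FN totals are equal, so
#' micro-averaged PPV always equals the overall accuracy.
#'
#' @param cm confusion matrix.
#' @return named numeric: `PPV`, `NPV`, `MCC`.
#' @export
microMetrics <- function(cm) {
  s <- colSums(.ovrCounts(cm))
  ppv <- s["TP"] / (s["TP"] + s["FP"])
  npv <- s["TN"] / (s["TN"] + s["FN"])
  denom <- sqrt(prod(c(s["TP"] + s["FP"], s["TP"] + s["FN"],
                       s["TN"] + s["FP"], s["TN"] + s["FN"])))
  mcc <- if (denom == 0) {
    message("degenerate MCC denominator: reporting 0")
    0
  } else (s["TP"] * s["TN"] - s["FP"] * s["FN"]) / denom
  c(PPV = unname(ppv), NPV = unname(npv), MCC = unname(mcc))
}

#' Full metrics report
#'
#' Accuracy, per-class rates and micro-averaged metrics, as fractions and
#' percentages (1 decimal).
#'
#' @param cm confusion matrix, or `actual` labels when `predicted` is given.
#' @param predicted optional predicted labels.
#' @return list of class `MetricsReport` with `confusion`, `accuracy`,
#'   `perClass`, `micro` and `percent` (rounded percentage view).
#' @export
metricsReport <- function(cm, predicted = NULL) {
  if (!is.null(predicted)) cm <- confusionMatrix(cm, predicted)
  acc <- accuracyFromCM(cm)
  per <- perClassRates(cm)
  mic <- microMetrics(cm)
  structure(list(
    confusion = cm, accuracy = acc, perClass = per, micro = mic,
    percent = list(
      accuracy = round(100 * acc, 1),
      sensitivity = round(100 * per$sensitivity, 1),
      specificity = round(100 * per$specificity, 1),
      PPV = round(100 * mic["PPV"], 1), NPV = round(100 * mic["NPV"], 1),
      MCC = round(100 * mic["MCC"], 1))), class = "MetricsReport")
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat("Confusion matrix (rows = actual, cols = predicted):\n")
  print(x$confusion)
  cat(sprintf("\nAccuracy: %.1f%%\n", 100 * x$accuracy))
  for (i in seq_len(nrow(x$perClass)))
    cat(sprintf("  %s: sensitivity %.1f%%, specificity %.1f%%\n",
                x$perClass$class[i], 100 * x$perClass$sensitivity[i],
                100 * x$perClass$specificity[i]))
  cat(sprintf("Micro PPV %.1f%%, NPV %.1f%%, MCC %.1f%%\n",
              100 * x$micro["PPV"], 100 * x$micro["NPV"], 100 * x$micro["MCC"]))
  invisible(x)
}

#' Write a confusion matrix as CSV
#'
#' Actual classes as rows, predicted as columns.
#'
#' @param cm confusion matrix.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeConfusionCSV <- function(cm, path) {
  df <- data.frame(actual = rownames(cm), as.data.frame.matrix(cm),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
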