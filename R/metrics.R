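# Confusion-matrix construction and the nine evaluation metrics:
# accuracy, sensitivity, specificity, precision, F1, Matthews correlation,
# Cohen's kappa, critical success index, Fowlkes-Mallows index. All are
# reported on a 0-100 percent scale (including MCC and kappa, x100) to
# match the conventional presentation; raw-scale values are available via
# `percent = FALSE`. Any 0/0 ratio is defined as 0.

#' Build a binary confusion matrix
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param positive the positive-class label (default `"seizure"`).
#' @return a `confusion_matrix` with integer fields `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(y_true, y_pred, positive = "seizure") {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred))
    stop_seizr("y_true and y_pred must have equal length", "seizr_param")
  assert_that(length(y_true) >= 1L, "need at least one label")
  tp <- y_true == positive
  pp <- y_pred == positive
  structure(list(TP = sum(tp & pp), FP = sum(!tp & pp),
                 TN = sum(!tp & !pp), FN = sum(tp & !pp),
                 positive = positive),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> TP=%d FP=%d TN=%d FN=%d (positive=%s)\n",
              x$TP, x$FP, x$TN, x$FN, x$positive))
  invisible(x)
}

safe_div <- function(num, den) if (den == 0) 0 else num / den

#' Compute the nine classification metrics
#'
#' @param cm a `confusion_matrix` (or list with TP, FP, TN, FN).
#' @param percent report on the 0-100 scale (default); `FALSE` gives raw
#'   proportions with MCC/kappa in `[-1, 1]`.
#' @return a `metrics_report`: named numeric vector with elements
#'   `accuracy`, `sensitivity`, `specificity`, `precision`, `f1`, `mcc`,
#'   `kappa`, `csi`, `fm_index`.
#' @export
compute_metrics <- function(cm, percent = TRUE) {
  TP <- cm$TP; FP <- cm$FP; TN <- cm$TN; FN <- cm$FN
  total <- TP + FP + TN + FN
  assert_that(total >= 1L, "confusion matrix is empty")
  accuracy <- (TP + TN) / total
  sensitivity <- safe_div(TP, TP + FN)
  specificity <- safe_div(TN, TN + FP)
  precision <- safe_div(TP, TP + FP)
  f1 <- safe_div(2 * precision * sensitivity, precision + sensitivity)
  mcc_den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  mcc <- if (mcc_den == 0) 0 else (TP * TN - FP * FN) / mcc_den
  p_o <- accuracy
  p_e <- ((TP + FP) * (TP + FN) + (FN + TN) * (FP + TN)) / total^2
  kappa <- if (p_e == 1) 0 else (p_o - p_e) / (1 - p_e)
  csi <- safe_div(TP, TP + FP + FN)
  fm <- sqrt(precision * sensitivity)
  out <- c(accuracy = accuracy, sensitivity = sensitivity,
           specificity = specificity, precision = precision, f1 = f1,
           mcc = mcc, kappa = kappa, csi = csi, fm_index = fm)
  if (percent) out <- out * 100
  structure(out, class = c("metrics_report", "numeric"))
}

#' @export
print.metrics_report <- function(x, ...) {
  df <- data.frame(metric = names(x), value = sprintf("%.2f", unclass(x)))
  print(df, row.names = FALSE)
  invisible(x)
}

#' F1 score from precision and sensitivity (percent scale)
#'
#' Harmonic mean; inputs and output on the 0-100 scale. Both zero maps to
#' 0 by convention.
#'
#' @param precision_pct,sensitivity_pct values in `[0, 100]`.
#' @return F1 on the 0-100 scale.
#' @export
f1_from_pr <- function(precision_pct, sensitivity_pct) {
  stopifnot(precision_pct >= 0, precision_pct <= 100,
            sensitivity_pct >= 0, sensitivity_pct <= 100)
  if (precision_pct + sensitivity_pct == 0) return(0)
  2 * precision_pct * sensitivity_pct / (precision_pct + sensitivity_pct)
}

#' Fowlkes-Mallows index from precision and sensitivity (percent scale)
#'
#' Geometric mean; inputs and output on the 0-100 scale.
#'
#' @inheritParams f1_from_pr
#' @return FM index on the 0-100 scale.
#' @export
fm_from_pr <- function(precision_pct, sensitivity_pct) {
  stopifnot(precision_pct >= 0, precision_pct <= 100,
            sensitivity_pct >= 0, sensitivity_pct <= 100)
  sqrt(precision_pct * sensitivity_pct)
}

#' Render one or more metric reports as a tab-separated table
#'
#' Rows follow the conventional order: accuracy, sensitivity, specificity,
#' precision, F1, MCC, kappa, CSI, FM index; one column per report.
#'
#' @param reports named list of `metrics_report` objects.
#' @param path optional output file; if `NULL` the data frame is returned
#'   only.
#' @return the rendered data frame (metric column plus one column per
#'   report, values rounded to 2 decimals).
#' @export
render_metrics_table <- function(reports, path = NULL) {
  if (inherits(reports, "metrics_report")) reports <- list(report = reports)
  df <- data.frame(metric = names(reports[[1]]))
  for (nm in names(reports)) df[[nm]] <- round(unclass(reports[[nm]]), 2)
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  df
}
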