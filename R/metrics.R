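# Confusion-matrix metrics for binary activity classification.
# The active class is the positive class throughout.

#' Confusion-matrix metrics (SE, SP, Q, MCC)
#'
#' Sensitivity `SE = TP/(TP+FN)`, specificity `SP = TN/(TN+FP)`, overall
#' accuracy `Q = (TP+TN)/n` and the Matthews correlation coefficient.  When
#' any factor of the MCC denominator is zero the coefficient is defined as 0
#' (the usual convention, keeping degenerate all-one-class predictions
#' finite).
#'
#' @param y_true,y_pred equal-length vectors over `{"active", "inactive"}`.
#' @return object of class `classification_metrics`: `tp`, `tn`, `fp`, `fn`,
#'   `se`, `sp`, `q`, `mcc`.
#' @export
confusion_metrics <- function(y_true, y_pred) {
  if (length(y_true) == 0L) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("label vectors differ in length")
  lv <- c("active", "inactive")
  if (!all(y_true %in% lv) || !all(y_pred %in% lv)) {
    stop("labels must be 'active' or 'inactive'")
  }
  tp <- sum(y_true == "active" & y_pred == "active")
  tn <- sum(y_true == "inactive" & y_pred == "inactive")
  fp <- sum(y_true == "inactive" & y_pred == "active")
  fn <- sum(y_true == "active" & y_pred == "inactive")
  se <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  q <- (tp + tn) / (tp + tn + fp + fn)
  denom <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0) {
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom)
  } else 0
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 se = se, sp = sp, q = q, mcc = mcc),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, digits = 3, ...) {
  cat(sprintf("TP=%d TN=%d FP=%d FN=%d | SE=%.*f SP=%.*f Q=%.*f MCC=%.*f\n",
              x$tp, x$tn, x$fp, x$fn, digits, x$se, digits, x$sp,
              digits, x$q, digits, x$mcc))
  invisible(x)
}

#' @export
as.data.frame.classification_metrics <- function(x, ...) {
  data.frame(tp = x$tp, tn = x$tn, fp = x$fp, fn = x$fn,
             se = x$se, sp = x$sp, q = x$q, mcc = x$mcc)
}
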