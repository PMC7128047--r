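# Pixelwise evaluation of a segmentation against ground truth, restricted to
# the camera field of view.

#' Confusion counts inside the FOV
#'
#' @param pred predicted vessel mask (logical matrix).
#' @param truth ground-truth vessel mask.
#' @param fov logical FOV mask; only `TRUE` pixels are counted.
#' @return object of class `confusion_counts` with integers `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
confusion <- function(pred, truth, fov = NULL) {
  pred <- as_mask(pred); truth <- as_mask(truth)
  check_same_shape(pred, truth, "prediction and truth")
  if (is.null(fov)) fov <- matrix(TRUE, nrow(pred), ncol(pred))
  fov <- as_mask(fov)
  check_same_shape(pred, fov, "prediction and FOV mask")
  p <- pred[fov]; t <- truth[fov]
  structure(list(tp = sum(p & t), fp = sum(p & !t),
                 tn = sum(!p & !t), fn = sum(!p & t)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion: TP=%d FP=%d TN=%d FN=%d\n", x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Sensitivity, specificity and accuracy
#'
#' `Se = TP/(TP+FN)`, `Sp = TN/(TN+FP)`, `Acc = (TP+TN)/(TP+FN+TN+FP)`.
#'
#' @param c `confusion_counts` object.
#' @return object of class `metric_report` with `sensitivity`,
#'   `specificity`, `accuracy`.
#' @export
metrics <- function(c) {
  if (!inherits(c, "confusion_counts")) stopf("metrics expects confusion_counts")
  if (c$tp + c$fn == 0) stopf("undefined metric: no positive (vessel) pixels in the truth")
  if (c$tn + c$fp == 0) stopf("undefined metric: no negative (background) pixels in the truth")
  structure(list(sensitivity = c$tp / (c$tp + c$fn),
                 specificity = c$tn / (c$tn + c$fp),
                 accuracy = (c$tp + c$tn) / (c$tp + c$fn + c$tn + c$fp),
                 counts = c),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("Se = %.4f  Sp = %.4f  Acc = %.4f\n",
              x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

#' Dice overlap coefficient
#'
#' `2 |A & B| / (|A| + |B|)` inside the FOV; 1 when both masks are empty.
#'
#' @param pred predicted mask.
#' @param truth ground-truth mask.
#' @param fov optional FOV mask.
#' @return scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(pred, truth, fov = NULL) {
  pred <- as_mask(pred); truth <- as_mask(truth)
  check_same_shape(pred, truth, "prediction and truth")
  if (!is.null(fov)) {
    fov <- as_mask(fov)
    pred <- pred & fov; truth <- truth & fov
  }
  denom <- sum(pred) + sum(truth)
  if (denom == 0) return(1)
  2 * sum(pred & truth) / denom
}

#' Average per-image metric reports
#'
#' Arithmetic mean of sensitivity, specificity and accuracy across images.
#'
#' @param reports list of `metric_report` objects.
#' @return `metric_report` with the averaged values (no counts).
#' @export
average_metrics <- function(reports) {
  if (!length(reports)) stopf("no metric reports to average")
  structure(list(sensitivity = mean(vapply(reports, `[[`, 0, "sensitivity")),
                 specificity = mean(vapply(reports, `[[`, 0, "specificity")),
                 accuracy = mean(vapply(reports, `[[`, 0, "accuracy")),
                 counts = NULL),
            class = "metric_report")
}
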