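# Confusion-based segmentation metrics (root = positive class), per-class
# and mean reporting, and the validation threshold sweep.

#' Pixel confusion counts
#'
#' @param pred,gt Binary arrays of identical shape; root = 1.
#' @return Named integer vector `TP`, `FP`, `FN`, `TN`.
#' @export
confusion_counts <- function(pred, gt) {
  if (!identical(dim(pred) %||% length(pred), dim(gt) %||% length(gt)))
    stop_invalid("prediction and ground truth shapes differ")
  if (!is_binary(pred) || !is_binary(gt))
    stop_invalid("confusion_counts expects binary inputs")
  tp <- sum(pred == 1 & gt == 1)
  fp <- sum(pred == 1 & gt == 0)
  fn <- sum(pred == 0 & gt == 1)
  c(TP = tp, FP = fp, FN = fn, TN = length(pred) - tp - fp - fn)
}

# Ratio with the degenerate-case rule: 0/0 counts as perfect agreement (1)
# when every count in the formula is zero, otherwise a zero numerator wins.
safe_ratio <- function(num, den) {
  if (den == 0) return(if (num == 0) 1 else 0)
  num / den
}

class_metrics <- function(tp, fp, fn) {
  P <- safe_ratio(tp, tp + fp)
  R <- safe_ratio(tp, tp + fn)
  c(iou = safe_ratio(tp, tp + fp + fn),
    precision = P,
    recall = R,
    f1 = if (P + R == 0) 0 else 2 * P * R / (P + R))
}

#' Per-class and mean segmentation metrics
#'
#' IoU = TP/(TP+FP+FN), Precision = TP/(TP+FP), Recall = TP/(TP+FN),
#' F1 = harmonic mean of P and R; the background row swaps class roles and
#' means are unweighted two-class averages.
#'
#' @param counts Output of [confusion_counts()] (or a sum of several).
#' @return List of class `metric_report` with `root`, `background`, `mean`
#'   (each named vectors `iou`/`precision`/`recall`/`f1`).
#' @export
seg_metrics <- function(counts) {
  if (sum(counts) == 0) stop_invalid("no evaluated pixels")
  root <- class_metrics(counts[["TP"]], counts[["FP"]], counts[["FN"]])
  bg <- class_metrics(counts[["TN"]], counts[["FN"]], counts[["FP"]])
  structure(list(root = root, background = bg, mean = (root + bg) / 2,
                 counts = counts),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  m <- rbind(R = x$root, B = x$background, m = x$mean) * 100
  colnames(m) <- c("IoU/%", "Precision/%", "Recall/%", "F1/%")
  print(round(m, 2))
  invisible(x)
}

#' Validation threshold sweep
#'
#' Binarizes probability maps at each threshold 0.1, 0.2, ..., 0.9,
#' accumulates confusion counts over the whole dataset (micro aggregation),
#' and returns the threshold with the highest mean IoU (ties broken toward
#' the smallest threshold).
#'
#' @param probs List of probability arrays (values in `[0, 1]`).
#' @param gts List of binary masks, aligned with `probs`.
#' @param thresholds Numeric vector of cutoffs (default `seq(0.1, 0.9, 0.1)`).
#' @return List with `threshold`, `report` (the [seg_metrics()] at the best
#'   threshold), `miou` (named vector over all thresholds).
#' @export
threshold_sweep <- function(probs, gts, thresholds = seq(0.1, 0.9, by = 0.1)) {
  if (length(probs) == 0L) stop_invalid("empty dataset")
  if (length(probs) != length(gts)) stop_invalid("probs/gts length mismatch")
  miou <- numeric(length(thresholds))
  reports <- vector("list", length(thresholds))
  for (i in seq_along(thresholds)) {
    acc <- c(TP = 0, FP = 0, FN = 0, TN = 0)
    for (j in seq_along(probs)) {
      pred <- (probs[[j]] >= thresholds[i]) * 1
      acc <- acc + confusion_counts(pred, gts[[j]])
    }
    reports[[i]] <- seg_metrics(acc)
    miou[i] <- reports[[i]]$mean[["iou"]]
  }
  names(miou) <- format(thresholds)
  best <- which.max(miou)   # first maximum = smallest threshold on ties
  list(threshold = thresholds[best], report = reports[[best]], miou = miou)
}

#' Relative excess of one F1 score over another
#'
#' `(f1_a - f1_b) / f1_b`, truncated toward zero at two decimals -- the
#' "exceeds by x times" arithmetic used when comparing root F1 scores
#' between models.
#'
#' @param f1_a,f1_b F1 scores (any common scale, e.g. percent).
#' @return The truncated excess ratio.
#' @export
f1_excess_ratio <- function(f1_a, f1_b) {
  if (f1_b == 0) stop_invalid("reference F1 is zero; ratio undefined")
  trunc((f1_a - f1_b) / f1_b * 100) / 100
}
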