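# Pixel-level evaluation: confusion matrix and the derived scores
# (per-class pixel accuracy, mPA, precision, mIoU, recall, F1).

#' Pixel confusion matrix
#'
#' `counts[t, p]` is the number of pixels with true class `t - 1` predicted
#' as class `p - 1`.
#'
#' @param pred,truth Integer matrices/vectors of equal shape, values in
#'   `0..C-1`.
#' @param num_classes Number of classes C.
#' @return `C x C` integer matrix of class `acu_confusion`.
#' @export
confusion_matrix <- function(pred, truth, num_classes) {
  if (length(pred) == 0L || length(truth) == 0L)
    stop("empty masks", call. = FALSE)
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth))
    stop("pred and truth shapes disagree", call. = FALSE)
  p <- as.integer(pred)
  t <- as.integer(truth)
  if (any(p < 0L | p >= num_classes) || any(t < 0L | t >= num_classes))
    stop("class values out of range 0..C-1", call. = FALSE)
  cm <- matrix(tabulate(t * num_classes + p + 1L, num_classes^2),
               num_classes, num_classes, byrow = TRUE)
  dimnames(cm) <- list(truth = 0:(num_classes - 1L),
                       pred = 0:(num_classes - 1L))
  class(cm) <- c("acu_confusion", class(cm))
  cm
}

#' Segmentation metrics from a confusion matrix
#'
#' Per class: pixel accuracy `PA = TP / (TP + FN)`, `IoU = TP /
#' (TP + FP + FN)`, `Precision = TP / (TP + FP)`, `Recall = TP /
#' (TP + FN)`.  Macro means run over all classes, background included;
#' classes absent from both truth and prediction have undefined ratios and
#' are skipped from the macro means (the number skipped is reported).  F1
#' is the harmonic mean of macro precision and macro recall.
#'
#' @param cm Confusion matrix from [confusion_matrix()].
#' @param foreground_only Average only foreground classes (drop class 0)
#'   in the macro means.
#' @return List of class `acu_metrics` with per-class vectors and macro
#'   scores, all fractions in `[0, 1]`.
#' @export
compute_metrics <- function(cm, foreground_only = FALSE) {
  cm <- unclass(cm)
  if (sum(cm) <= 0) stop("confusion matrix is empty", call. = FALSE)
  C <- nrow(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  pa <- tp / (tp + fn)
  iou <- tp / (tp + fp + fn)
  precision <- tp / (tp + fp)
  recall <- tp / (tp + fn)
  present <- (tp + fn + fp) > 0          # class seen in truth or prediction
  keep <- if (foreground_only) present & (seq_len(C) > 1L) else present
  skipped <- sum(!present)
  macro <- function(x) mean(x[keep], na.rm = TRUE)
  mprec <- macro(precision)
  mrec <- macro(recall)
  structure(list(
    per_class = data.frame(
      class = 0:(C - 1L), PA = pa, IoU = iou,
      Precision = precision, Recall = recall, row.names = NULL),
    mPA = macro(pa), mIoU = macro(iou),
    precision = mprec, recall = mrec,
    F1 = 2 * mprec * mrec / (mprec + mrec),
    skipped_classes = skipped,
    foreground_only = foreground_only),
    class = "acu_metrics")
}

#' @export
print.acu_metrics <- function(x, ...) {
  cat("segmentation metrics",
      if (x$foreground_only) "(foreground classes only)", "\n")
  df <- x$per_class
  df[-1] <- lapply(df[-1], function(v) sprintf("%.2f%%", 100 * v))
  print(df, row.names = FALSE)
  cat(sprintf("mPA %.2f%%  mIoU %.2f%%  Precision %.2f%%  Recall %.2f%%  F1 %.2f%%\n",
              100 * x$mPA, 100 * x$mIoU, 100 * x$precision,
              100 * x$recall, 100 * x$F1))
  if (x$skipped_classes > 0)
    cat(sprintf("(%d absent class(es) skipped from macro means)\n",
                x$skipped_classes))
  invisible(x)
}

#' Evaluate a model over a set of (image, mask) samples
#'
#' Accumulates one confusion matrix over all pixels of all samples and
#' derives the metric report.
#'
#' @param model An `acunet_model`.
#' @param samples List of `list(image=, mask=)` pairs.
#' @return List with `cm` and `metrics`.
#' @export
evaluate_model <- function(model, samples) {
  C <- model$config$num_classes
  cm <- matrix(0L, C, C)
  for (s in samples) {
    pred <- predict_mask(model, s$image)
    cm <- cm + unclass(confusion_matrix(pred, s$mask, C))
  }
  class(cm) <- c("acu_confusion", class(cm))
  list(cm = cm, metrics = compute_metrics(cm))
}
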