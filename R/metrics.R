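# Pixelwise segmentation metrics: confusion counts and the six derived
# scores (accuracy, precision, recall, specificity, Dice, IoU).

#' Pixelwise confusion counts
#'
#' @param pred,gt logical masks of equal shape; `TRUE` = nucleus foreground.
#' @return Named integer vector `(tp, tn, fp, fn)` summing to the pixel count.
#' @export
confusion_counts <- function(pred, gt) {
  validate_mask(pred); validate_mask(gt)
  if (!identical(dim(pred), dim(gt)))
    stop("dimension mismatch between predicted and ground-truth masks",
         call. = FALSE)
  tp <- sum(pred & gt)
  tn <- sum(!pred & !gt)
  fp <- sum(pred & !gt)
  fn <- sum(!pred & gt)
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

metric_from_counts <- function(tp, tn, fp, fn) {
  total <- tp + tn + fp + fn
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  vals <- c(accuracy    = ratio(tp + tn, total),
            precision   = ratio(tp, tp + fp),
            recall      = ratio(tp, tp + fn),
            specificity = ratio(tn, tn + fp),
            dsc         = ratio(2 * tp, 2 * tp + fp + fn),
            iou         = ratio(tp, tp + fp + fn))
  undefined <- names(vals)[is.na(vals)]
  vals[is.na(vals)] <- 0
  structure(c(list(tp = tp, tn = tn, fp = fp, fn = fn), as.list(vals),
              list(undefined = undefined)),
            class = "metric_report")
}

#' Evaluate a predicted mask against ground truth
#'
#' Computes the pixel confusion counts and the six standard segmentation
#' scores: accuracy `(TP+TN)/total`, precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)`, Dice similarity coefficient
#' `2TP/(2TP+FP+FN)` (the harmonic mean of precision and recall) and
#' intersection over union `TP/(TP+FP+FN)`. A ratio with zero denominator is
#' reported as 0 and listed in the report's `undefined` field.
#'
#' @param pred,gt logical masks of equal shape.
#' @return A `metric_report`: list with `tp`, `tn`, `fp`, `fn`, the six
#'   scores, and `undefined` (names of zero-denominator metrics).
#' @export
#' @examples
#' gt <- matrix(FALSE, 2, 5); gt[1, 1:4] <- TRUE
#' pred <- matrix(FALSE, 2, 5); pred[1, 1:3] <- TRUE; pred[2, 5] <- TRUE
#' evaluate_masks(pred, gt)$iou # 3 / (3 + 1 + 1)
evaluate_masks <- function(pred, gt) {
  cc <- confusion_counts(pred, gt)
  metric_from_counts(cc[["tp"]], cc[["tn"]], cc[["fp"]], cc[["fn"]])
}

#' @export
print.metric_report <- function(x, digits = 4, ...) {
  cat(sprintf("Pixel confusion: TP %d  TN %d  FP %d  FN %d\n",
              x$tp, x$tn, x$fp, x$fn))
  m <- unlist(x[c("accuracy", "precision", "recall", "specificity",
                  "dsc", "iou")])
  print(round(m, digits))
  if (length(x$undefined))
    cat("undefined (zero denominator, reported as 0):",
        paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.metric_report <- function(x, ...) {
  data.frame(tp = x$tp, tn = x$tn, fp = x$fp, fn = x$fn,
             accuracy = x$accuracy, precision = x$precision,
             recall = x$recall, specificity = x$specificity,
             dsc = x$dsc, iou = x$iou)
}

#' Batch evaluation over mask pairs
#'
#' Evaluates every (prediction, ground truth) pair and aggregates by the
#' unweighted mean over images.
#'
#' @param preds,gts lists of logical masks, matched by position or by name.
#' @return A list with `per_image` (data frame, one row per pair) and
#'   `aggregate` (named numeric vector of mean scores).
#' @export
evaluate_batch <- function(preds, gts) {
  if (length(preds) != length(gts))
    stop("pred/gt lists differ in length", call. = FALSE)
  if (!is.null(names(preds)) && !is.null(names(gts))) {
    if (!setequal(names(preds), names(gts)))
      stop("pred/gt names do not match", call. = FALSE)
    gts <- gts[names(preds)]
  }
  rows <- lapply(seq_along(preds), function(i)
    as.data.frame(evaluate_masks(preds[[i]], gts[[i]])))
  per_image <- do.call(rbind, rows)
  if (!is.null(names(preds))) per_image <- cbind(image = names(preds), per_image)
  score_cols <- c("accuracy", "precision", "recall", "specificity", "dsc", "iou")
  list(per_image = per_image,
       aggregate = colMeans(per_image[, score_cols, drop = FALSE]))
}

#' Batch evaluation of mask files on disk
#'
#' Reads two directories of single-channel PNG masks (0/255) matched by
#' filename and evaluates each pair.
#'
#' @param pred_dir,gt_dir directories of PNG masks.
#' @return As [evaluate_batch()].
#' @export
evaluate_dirs <- function(pred_dir, gt_dir) {
  files <- sort(intersect(list.files(pred_dir, pattern = "\\.png$"),
                          list.files(gt_dir, pattern = "\\.png$")))
  if (!length(files)) stop("no matching PNG pairs found", call. = FALSE)
  preds <- lapply(files, function(f) read_mask(file.path(pred_dir, f)))
  gts   <- lapply(files, function(f) read_mask(file.path(gt_dir, f)))
  names(preds) <- names(gts) <- files
  evaluate_batch(preds, gts)
}
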