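# Segmentation evaluation: per-class one-vs-rest confusion counts and the
# five standard metrics derived from them.

#' Per-class confusion counts between two label masks
#'
#' One-vs-rest pixel counts (TP, FP, FN, TN) for every class index in
#' `0:(n_classes - 1)`. Both masks must already be hard label maps (argmax
#' applied upstream).
#'
#' @param pred,gt `(H, W)` integer masks with 0-based class indices.
#' @param n_classes number of classes `K`.
#' @return a `data.frame` with columns `class`, `tp`, `fp`, `fn`, `tn`;
#'   rows sum to `H * W` for every class.
#' @export
confusion_counts <- function(pred, gt, n_classes) {
  if (!identical(dim(pred), dim(gt))) {
    stop("confusion_counts: mask shapes differ")
  }
  total <- length(gt)
  # joint tally over (pred, gt) pairs
  joint <- tabulate(as.vector(pred) * n_classes + as.vector(gt) + 1L,
                    nbins = n_classes^2)
  joint <- matrix(joint, nrow = n_classes, byrow = TRUE) # [pred+1, gt+1]
  tp <- diag(joint)
  fp <- rowSums(joint) - tp
  fn <- colSums(joint) - tp
  data.frame(class = 0:(n_classes - 1), tp = tp, fp = fp, fn = fn,
             tn = total - tp - fp - fn)
}

# shared both-empty convention: when a class is absent from prediction and
# ground truth alike, every metric is defined as 1 so that all-background
# images do not poison averages.
metric_ratio <- function(num, den, empty) {
  ifelse(empty, 1, ifelse(den == 0, 0, num / den))
}

#' @rdname segmentation_metrics
#' @export
iou <- function(counts) {
  with(counts, metric_ratio(tp, tp + fp + fn, tp + fp + fn == 0))
}

#' @rdname segmentation_metrics
#' @export
dsc <- function(counts) {
  with(counts, metric_ratio(2 * tp, 2 * tp + fp + fn, tp + fp + fn == 0))
}

#' @rdname segmentation_metrics
#' @export
accuracy <- function(counts) {
  with(counts, (tp + tn) / (tp + tn + fp + fn))
}

#' @rdname segmentation_metrics
#' @export
precision <- function(counts) {
  with(counts, metric_ratio(tp, tp + fp, tp + fp + fn == 0))
}

#' Segmentation metrics from confusion counts
#'
#' IoU `|G∩P| / |G∪P|`, Dice `2|G∩P| / (|G|+|P|)`, pixel accuracy,
#' precision and recall, each computed per class from one-vs-rest counts.
#' When a class is empty in both masks all metrics are 1 by convention;
#' otherwise a zero denominator yields 0. The identity
#' `DSC = 2*IoU / (1 + IoU)` holds exactly.
#'
#' @param counts output of [confusion_counts()].
#' @return numeric vector, one value per class.
#' @name segmentation_metrics
#' @export
recall <- function(counts) {
  with(counts, metric_ratio(tp, tp + fn, tp + fp + fn == 0))
}

#' Full evaluation of a predicted mask against ground truth
#'
#' Computes all five metrics per class plus macro averages. The macro IoU
#' and Dice exclude the background class 0; accuracy, precision and recall
#' macros average over foreground classes as well.
#'
#' @inheritParams confusion_counts
#' @return list with `per_class` (data.frame) and `macro` (named numeric).
#' @export
evaluate_segmentation <- function(pred, gt, n_classes) {
  cc <- confusion_counts(pred, gt, n_classes)
  per <- data.frame(class = cc$class, iou = iou(cc), dsc = dsc(cc),
                    accuracy = accuracy(cc), precision = precision(cc),
                    recall = recall(cc))
  fg <- per$class > 0
  macro <- vapply(per[fg, -1, drop = FALSE], mean, numeric(1))
  list(per_class = per, macro = macro)
}

#' Write an evaluation report as CSV
#'
#' One row per image and class, followed by macro-summary rows (class `NA`).
#'
#' @param preds,gts lists of `(H, W)` label masks.
#' @param n_classes number of classes.
#' @param path output CSV path, or `NULL` to skip writing.
#' @return the report data.frame, invisibly if written to disk.
#' @export
evaluation_report <- function(preds, gts, n_classes, path = NULL) {
  stopifnot(length(preds) == length(gts))
  rows <- lapply(seq_along(preds), function(i) {
    ev <- evaluate_segmentation(preds[[i]], gts[[i]], n_classes)
    rbind(cbind(image = i, ev$per_class),
          cbind(image = i, class = NA,
                as.data.frame(as.list(ev$macro))))
  })
  report <- do.call(rbind, rows)
  if (!is.null(path)) {
    write.csv(report, path, row.names = FALSE)
    return(invisible(report))
  }
  report
}
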