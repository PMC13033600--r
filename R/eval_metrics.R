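# Confusion-matrix metrics, Dice coefficient, detection matching and
# average precision at IoU 0.5.

#' Dice coefficient between two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; defined as 1.0 when both masks are
#' empty (both raters agree nothing is present).
#'
#' @param a,b [binary_mask] objects or 0/1 matrices of the same shape.
#' @return A value in [0, 1].
#' @export
dice_coefficient <- function(a, b) {
  ga <- if (inherits(a, "binary_mask")) a$grid else as.matrix(a)
  gb <- if (inherits(b, "binary_mask")) b$grid else as.matrix(b)
  if (!all(dim(ga) == dim(gb))) stop("mask shape mismatch")
  sa <- sum(ga != 0); sb <- sum(gb != 0)
  if (sa + sb == 0) return(1.0)
  2 * sum(ga != 0 & gb != 0) / (sa + sb)
}

#' Confusion counts
#'
#' @param tp,tn,fp,fn non-negative integer counts.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp = 0, tn = 0, fp = 0, fn = 0) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn),
            class = "confusion_counts")
}

#' Metrics derived from a confusion matrix
#'
#' Precision `tp / (tp + fp)`, recall `tp / (tp + fn)`, their harmonic mean
#' F1, and accuracy. A metric whose denominator is zero is undefined: it is
#' reported as `NA` with `undefined_flags` naming it, never silently as 0 —
#' except F1, which is reported as 0 (flagged) when precision and recall are
#' both 0.
#'
#' @param c a [confusion_counts].
#' @return `list(precision, recall, f1, accuracy, undefined_flags)`.
#' @export
confusion_metrics <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  flags <- character()
  precision <- if (c$tp + c$fp > 0) c$tp / (c$tp + c$fp) else {
    flags <- c(flags, "precision"); NA_real_
  }
  recall <- if (c$tp + c$fn > 0) c$tp / (c$tp + c$fn) else {
    flags <- c(flags, "recall"); NA_real_
  }
  f1 <- if (is.finite(precision) && is.finite(recall)) {
    if (precision + recall > 0) 2 * precision * recall / (precision + recall)
    else { flags <- c(flags, "f1"); 0 }
  } else { flags <- c(flags, "f1"); NA_real_ }
  total <- c$tp + c$tn + c$fp + c$fn
  accuracy <- if (total > 0) (c$tp + c$tn) / total else {
    flags <- c(flags, "accuracy"); NA_real_
  }
  list(precision = precision, recall = recall, f1 = f1, accuracy = accuracy,
       undefined_flags = flags)
}

#' Match detections to ground truth at an IoU threshold
#'
#' Detections are processed in order of decreasing confidence; each one
#' matches the not-yet-matched ground-truth box of highest IoU provided
#' IoU >= `iou_min` (a true positive), otherwise it is a false positive.
#' Ground-truth boxes left unmatched are false negatives.
#'
#' @param dets [detection_boxes] (needs `confidence`).
#' @param gts ground-truth boxes ([detection_boxes] or matrix x0, y0, x1, y1).
#' @param iou_min matching threshold (default 0.5).
#' @return `list(labels = <"TP"/"FP" per detection, in confidence order>,
#'   fn = <count>, order = <original indices in confidence order>)`.
#' @export
match_detections <- function(dets, gts, iou_min = 0.5) {
  G <- if (is.data.frame(gts)) as.matrix(gts[, c("x0", "y0", "x1", "y1")])
       else if (is.null(gts)) matrix(0, 0, 4) else as.matrix(gts)
  n_gt <- nrow(G)
  if (nrow(dets) == 0)
    return(list(labels = character(), fn = n_gt, order = integer()))
  ord <- order(-dets$confidence, seq_len(nrow(dets)))
  D <- as.matrix(dets[ord, c("x0", "y0", "x1", "y1")])
  taken <- rep(FALSE, n_gt)
  labels <- character(nrow(D))
  for (i in seq_len(nrow(D))) {
    if (n_gt == 0) { labels[i] <- "FP"; next }
    ious <- box_iou_vec(D[i, ], G)
    ious[taken] <- -1
    j <- which.max(ious)
    if (length(j) && ious[j] >= iou_min) {
      labels[i] <- "TP"; taken[j] <- TRUE
    } else labels[i] <- "FP"
  }
  list(labels = labels, fn = sum(!taken), order = ord)
}

#' Average precision from an ordered TP/FP sequence
#'
#' All-point interpolation: the area under the precision envelope (running
#' maximum of precision from the right) as a function of recall. With a
#' single class, mAP@0.5 equals AP@0.5.
#'
#' @param labels character vector of `"TP"` / `"FP"` in decreasing-confidence
#'   order.
#' @param n_gt number of ground-truth objects (>= 0).
#' @param interpolation `"all"` (default) or `"11point"`.
#' @return AP in [0, 1]. With no ground truth, AP is 1.0 if there are no
#'   detections and 0.0 otherwise.
#' @export
average_precision <- function(labels, n_gt, interpolation = c("all", "11point")) {
  interpolation <- match.arg(interpolation)
  stopifnot(n_gt >= 0)
  if (n_gt == 0) return(if (length(labels) == 0) 1.0 else 0.0)
  if (length(labels) == 0) return(0.0)
  tp <- cumsum(labels == "TP")
  fp <- cumsum(labels == "FP")
  recall <- tp / n_gt
  precision <- tp / (tp + fp)
  # precision envelope: running max from the right
  env <- rev(cummax(rev(precision)))
  if (interpolation == "11point") {
    r_levels <- seq(0, 1, by = 0.1)
    p_at <- vapply(r_levels, function(r) {
      ok <- recall >= r
      if (any(ok)) max(env[ok]) else 0
    }, 0)
    return(mean(p_at))
  }
  # area under the step curve: sum over recall increments
  r_prev <- c(0, recall[-length(recall)])
  sum((recall - r_prev) * env)
}

#' Full detection evaluation report
#'
#' @param dets,gts as in [match_detections].
#' @param iou_min IoU threshold (default 0.5).
#' @return `list(precision, recall, f1, accuracy, map50, counts)`.
#' @export
evaluate_detections <- function(dets, gts, iou_min = 0.5) {
  m <- match_detections(dets, gts, iou_min)
  cc <- confusion_counts(tp = sum(m$labels == "TP"),
                         fp = sum(m$labels == "FP"), fn = m$fn)
  mets <- confusion_metrics(cc)
  n_gt <- if (is.data.frame(gts)) nrow(gts) else if (is.null(gts)) 0 else nrow(as.matrix(gts))
  mets$map50 <- average_precision(m$labels, n_gt)
  mets$counts <- cc
  mets
}
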