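# VOC-style detection metrics: confusion counts, precision/recall,
# greedy IoU matching, precision-recall curve, per-class average
# precision and mAP.

#' Precision from confusion counts
#' @param tp,fp true / false positive counts.
#' @return `TP / (TP + FP)`.
#' @export
precision <- function(tp, fp) {
  if (tp + fp <= 0) stop("precision undefined when TP + FP = 0", call. = FALSE)
  tp / (tp + fp)
}

#' Recall from confusion counts
#' @param tp,fn true positive / false negative counts.
#' @return `TP / (TP + FN)`.
#' @export
recall <- function(tp, fn) {
  if (tp + fn <= 0) stop("recall undefined without ground truth", call. = FALSE)
  tp / (tp + fn)
}

#' Greedy IoU matching of detections to ground truth
#'
#' Detections are processed in descending score order; each one matches
#' the highest-IoU not-yet-matched ground-truth box of its class with
#' IoU at or above the threshold (true positive), otherwise it is a
#' false positive. Each ground-truth box matches at most once.
#'
#' @param dets data.frame with `class_id, score, x1, y1, x2, y2`.
#' @param gts data.frame with `class_id, x1, y1, x2, y2`.
#' @param iou_thresh matching threshold.
#' @return `dets` (sorted by descending score) with logical column `tp`
#'   and `matched_gt` (row index into `gts`, NA for false positives).
#' @export
match_detections <- function(dets, gts, iou_thresh = 0.5) {
  dets <- dets[order(-dets$score), , drop = FALSE]
  tp <- logical(nrow(dets))
  matched_gt <- rep(NA_integer_, nrow(dets))
  used <- logical(nrow(gts))
  for (i in seq_len(nrow(dets))) {
    cand <- which(!used & gts$class_id == dets$class_id[[i]])
    if (!length(cand)) next
    ious <- box_iou(unlist(dets[i, c("x1", "y1", "x2", "y2")]),
                    gts[cand, , drop = FALSE])
    j <- which.max(ious)
    if (ious[[j]] >= iou_thresh) {
      tp[[i]] <- TRUE
      matched_gt[[i]] <- cand[[j]]
      used[[cand[[j]]]] <- TRUE
    }
  }
  dets$tp <- tp
  dets$matched_gt <- matched_gt
  dets
}

#' Average precision from scored true/false-positive labels
#'
#' All-point interpolation: the precision envelope is made monotone
#' non-increasing in recall and integrated over the recall increments
#' (the area enclosed by the P-R curve). The 11-point VOC-2007 variant
#' is available as an option.
#'
#' @param scores detection scores.
#' @param tp logical true-positive labels, same length.
#' @param n_gt number of ground-truth boxes of the class (> 0).
#' @param interpolation `"all"` (default) or `"voc11"`.
#' @return list with `ap`, `precision`, `recall` (curve points).
#' @export
average_precision <- function(scores, tp, n_gt,
                              interpolation = c("all", "voc11")) {
  interpolation <- match.arg(interpolation)
  if (n_gt <= 0) stop("average precision undefined without ground truth",
                      call. = FALSE)
  if (length(scores) == 0) {
    return(list(ap = 0, precision = numeric(0), recall = numeric(0)))
  }
  ord <- order(-scores)
  tp <- as.logical(tp)[ord]
  ctp <- cumsum(tp)
  cfp <- cumsum(!tp)
  prec <- ctp / (ctp + cfp)
  rec <- ctp / n_gt
  if (interpolation == "voc11") {
    ap <- mean(vapply(seq(0, 1, by = 0.1), function(r) {
      p <- prec[rec >= r]
      if (length(p)) max(p) else 0
    }, numeric(1)))
  } else {
    env <- rev(cummax(rev(prec)))
    r_prev <- c(0, rec[-length(rec)])
    ap <- sum((rec - r_prev) * env)
  }
  list(ap = ap, precision = prec, recall = rec)
}

#' Mean average precision
#' @param aps numeric vector of per-class AP values.
#' @return arithmetic mean.
#' @export
mean_ap <- function(aps) {
  stopifnot(length(aps) >= 1)
  mean(aps)
}

#' Evaluate detections over a set of images
#'
#' @param pred_list list of detection data.frames (one per image), each
#'   with `class_id, score, x1, y1, x2, y2`.
#' @param gt_list list of ground-truth data.frames (one per image) with
#'   `class_id, x1, y1, x2, y2`.
#' @param iou_thresh matching IoU threshold.
#' @param class_names names for the class ids (0-based order).
#' @param interpolation passed to [average_precision()].
#' @return list with `per_class` (AP and P-R points per class) and `map`.
#' @export
evaluate_detections <- function(pred_list, gt_list, iou_thresh = 0.5,
                                class_names = c("fertile", "infertile"),
                                interpolation = "all") {
  stopifnot(length(pred_list) == length(gt_list))
  rows <- list()
  n_gt <- setNames(numeric(length(class_names)), class_names)
  for (i in seq_along(pred_list)) {
    gts <- gt_list[[i]]
    for (ci in seq_along(class_names) - 1L) {
      n_gt[[ci + 1L]] <- n_gt[[ci + 1L]] + sum(gts$class_id == ci)
    }
    dets <- pred_list[[i]]
    if (is.null(dets) || nrow(dets) == 0) next
    m <- match_detections(dets, gts, iou_thresh)
    rows[[length(rows) + 1L]] <-
      data.frame(class_id = m$class_id, score = m$score, tp = m$tp)
  }
  all <- if (length(rows)) do.call(rbind, rows) else
    data.frame(class_id = integer(0), score = numeric(0), tp = logical(0))
  per_class <- list()
  aps <- numeric(0)
  for (ci in seq_along(class_names) - 1L) {
    nm <- class_names[[ci + 1L]]
    if (n_gt[[nm]] == 0) next
    sub <- all[all$class_id == ci, , drop = FALSE]
    pc <- average_precision(sub$score, sub$tp, n_gt[[nm]], interpolation)
    per_class[[nm]] <- pc
    aps <- c(aps, pc$ap)
  }
  list(per_class = per_class, map = mean_ap(aps))
}
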