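#' Precision and recall from match counts
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`; a zero denominator yields 0
#' by convention (no detections means no correct detections).
#'
#' @param tp,fp,fn Nonnegative counts.
#' @return A list with `precision` and `recall`.
#' @export
precision_recall <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  list(precision = if (tp + fp > 0) tp / (tp + fp) else 0,
       recall = if (tp + fn > 0) tp / (tp + fn) else 0)
}

# Greedy confidence-ranked matching for one class: returns logical TP flags
# aligned with detections sorted by decreasing confidence, plus n_gt.
rank_detections <- function(det, gt, iou_threshold) {
  ord <- order(-det$conf)
  det <- det[ord, , drop = FALSE]
  tp <- logical(nrow(det))
  used <- rep(FALSE, nrow(gt))
  if (nrow(gt)) {
    gt_by_frame <- split(seq_len(nrow(gt)), gt$frame)
    for (i in seq_len(nrow(det))) {
      cand <- gt_by_frame[[as.character(det$frame[i])]]
      cand <- cand[!used[cand]]
      if (!length(cand)) next
      ious <- iou_matrix(as.matrix(det[i, c("x1", "y1", "x2", "y2")]),
                         as.matrix(gt[cand, c("x1", "y1", "x2", "y2")]))[1, ]
      j <- which.max(ious)
      if (ious[j] >= iou_threshold) {
        tp[i] <- TRUE
        used[cand[j]] <- TRUE
      }
    }
  }
  list(tp = tp, n_gt = nrow(gt))
}

#' Average precision at one IoU threshold
#'
#' Detections are ranked by confidence and matched greedily (each ground
#' truth consumed at most once, highest-overlap candidate first, overlap at
#' least `iou_threshold`); AP is the area under the interpolated
#' precision-recall curve using continuous all-points interpolation (the
#' precision envelope integrated over every recall step).
#'
#' @param det `data.frame(frame, x1, y1, x2, y2, conf)` of scored detections.
#' @param gt `data.frame(frame, x1, y1, x2, y2)` of ground-truth boxes.
#' @param iou_threshold Matching threshold in `(0, 1)`.
#' @return AP in `[0, 1]` (0 when there are no detections or no truths).
#' @export
average_precision <- function(det, gt, iou_threshold = 0.5) {
  if (nrow(det) == 0L || nrow(gt) == 0L) return(0)
  r <- rank_detections(det, gt, iou_threshold)
  tp_cum <- cumsum(r$tp)
  fp_cum <- cumsum(!r$tp)
  recall <- tp_cum / r$n_gt
  precision <- tp_cum / (tp_cum + fp_cum)
  # precision envelope, integrated over recall
  penv <- rev(cummax(rev(precision)))
  dr <- diff(c(0, recall))
  sum(dr * penv)
}

#' Mean average precision suite
#'
#' Per-class AP at IoU 0.5 and averaged over the IoU grid 0.5 to 0.95 in
#' steps of 0.05; class-averaged to mAP. Classes present in the ground truth
#' define the averaging set; a class with truths but no detections
#' contributes AP 0.
#'
#' @param det `data.frame(frame, x1, y1, x2, y2, conf, class_id)`.
#' @param gt `data.frame(frame, x1, y1, x2, y2, class_id)`.
#' @param thresholds IoU grid for the strict average (default
#'   `seq(0.5, 0.95, 0.05)`).
#' @return A list with `mAP50`, `mAP50_95` and `per_class`
#'   (`data.frame(class_id, AP50, AP50_95)`).
#' @export
map_suite <- function(det, gt, thresholds = seq(0.5, 0.95, by = 0.05)) {
  classes <- sort(unique(gt$class_id))
  per <- lapply(classes, function(cl) {
    dcl <- det[det$class_id == cl, , drop = FALSE]
    gcl <- gt[gt$class_id == cl, , drop = FALSE]
    aps <- vapply(thresholds, function(t) average_precision(dcl, gcl, t), 1)
    c(AP50 = aps[which.min(abs(thresholds - 0.5))], AP50_95 = mean(aps))
  })
  tab <- data.frame(class_id = classes,
                    AP50 = vapply(per, `[[`, 1, "AP50"),
                    AP50_95 = vapply(per, `[[`, 1, "AP50_95"))
  list(mAP50 = mean(tab$AP50), mAP50_95 = mean(tab$AP50_95),
       per_class = tab)
}
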