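#' Evaluation configuration
#'
#' @param alpha IoU threshold for the CLEAR metrics (MOTA/MOTP) and IDF1
#'   (default 0.5).
#' @param hota_alphas Threshold grid for HOTA (default 0.05 to 0.95 in steps
#'   of 0.05).
#' @return A list of class `"eval_config"`.
#' @export
eval_config <- function(alpha = 0.5, hota_alphas = seq(0.05, 0.95, by = 0.05)) {
  stopifnot(alpha > 0, alpha < 1, all(hota_alphas > 0), all(hota_alphas < 1))
  structure(list(alpha = alpha, hota_alphas = hota_alphas),
            class = "eval_config")
}

traj_boxes <- function(df) as.matrix(df[, c("x1", "y1", "x2", "y2")])

#' Match one frame's ground truth against predictions
#'
#' One-to-one matching maximising total IoU subject to IoU at least
#' `threshold` (Hungarian on `1 - IoU` with gating), with the standard
#' CLEAR continuity preference: a ground truth keeps its previous frame's
#' partner whenever that pairing still clears the threshold, and only the
#' remainder is re-optimised.
#'
#' @param gt_boxes `n x 4` matrix of ground-truth boxes.
#' @param pred_boxes `m x 4` matrix of predicted boxes.
#' @param threshold Minimum IoU for a valid match.
#' @param prev Optional 2-column matrix of `(gt_row, pred_row)` pairs to
#'   prefer for continuity.
#' @return A list with `matches` (`data.frame(gt, pred, iou)`),
#'   `unmatched_gt` and `unmatched_pred` (row indices).
#' @export
match_frame <- function(gt_boxes, pred_boxes, threshold = 0.5, prev = NULL) {
  if (is.null(dim(gt_boxes))) gt_boxes <- matrix(gt_boxes, ncol = 4L)
  if (is.null(dim(pred_boxes))) pred_boxes <- matrix(pred_boxes, ncol = 4L)
  n <- nrow(gt_boxes); m <- nrow(pred_boxes)
  ious <- iou_matrix(gt_boxes, pred_boxes)
  keep_g <- integer(0); keep_p <- integer(0)
  if (!is.null(prev) && nrow(prev)) {
    for (r in seq_len(nrow(prev))) {
      g <- prev[r, 1]; p <- prev[r, 2]
      if (g >= 1 && g <= n && p >= 1 && p <= m &&
          !(g %in% keep_g) && !(p %in% keep_p) &&
          ious[g, p] >= threshold) {
        keep_g <- c(keep_g, g); keep_p <- c(keep_p, p)
      }
    }
  }
  rem_g <- setdiff(seq_len(n), keep_g)
  rem_p <- setdiff(seq_len(m), keep_p)
  add_g <- integer(0); add_p <- integer(0)
  if (length(rem_g) && length(rem_p)) {
    cost <- 1 - ious[rem_g, rem_p, drop = FALSE]
    cost[ious[rem_g, rem_p, drop = FALSE] < threshold] <- Inf
    sol <- solve_assignment(cost)
    add_g <- rem_g[sol$rows]; add_p <- rem_p[sol$cols]
  }
  mg <- c(keep_g, add_g); mp <- c(keep_p, add_p)
  list(matches = data.frame(gt = mg, pred = mp,
                            iou = if (length(mg)) ious[cbind(mg, mp)]
                                  else numeric(0)),
       unmatched_gt = setdiff(seq_len(n), mg),
       unmatched_pred = setdiff(seq_len(m), mp))
}

split_frames <- function(df) split(seq_len(nrow(df)), df$frame)

#' CLEAR tracking metrics: MOTA, MOTP, identity switches
#'
#' `MOTA = (1 - (FN + FP + IDSW) / n_gt) * 100` with the per-frame
#' continuity-preserving matching of [match_frame()]; an identity switch is
#' counted whenever a matched ground truth's partner id differs from its
#' most recent one. `MOTP` is the mean IoU over all matches, times 100
#' (similarity convention).
#'
#' @param gt,pred Trajectory sets: `data.frame(frame, id, x1, y1, x2, y2)`.
#' @param cfg An [eval_config()].
#' @return A list with `MOTA`, `MOTP`, `IDs`, `FP`, `FN`, `TP`, `n_gt`.
#' @export
mota_motp <- function(gt, pred, cfg = eval_config()) {
  thr <- cfg$alpha
  gtf <- split_frames(gt); prf <- split_frames(pred)
  frames <- sort(unique(c(gt$frame, pred$frame)))
  last_match <- new.env(parent = emptyenv())
  fn <- 0L; fp <- 0L; idsw <- 0L; tp <- 0L; iou_sum <- 0
  for (f in frames) {
    gi <- gtf[[as.character(f)]] %||% integer(0)
    pi <- prf[[as.character(f)]] %||% integer(0)
    if (!length(gi)) { fp <- fp + length(pi); next }
    if (!length(pi)) { fn <- fn + length(gi); next }
    gids <- gt$id[gi]; pids <- pred$id[pi]
    prev <- NULL
    for (k in seq_along(gids)) {
      lp <- last_match[[as.character(gids[k])]]
      if (!is.null(lp) && lp %in% pids)
        prev <- rbind(prev, c(k, match(lp, pids)))
    }
    mm <- match_frame(traj_boxes(gt[gi, , drop = FALSE]),
                      traj_boxes(pred[pi, , drop = FALSE]), thr, prev)
    fn <- fn + length(mm$unmatched_gt)
    fp <- fp + length(mm$unmatched_pred)
    tp <- tp + nrow(mm$matches)
    iou_sum <- iou_sum + sum(mm$matches$iou)
    if (nrow(mm$matches)) {
      for (r in seq_len(nrow(mm$matches))) {
        g <- as.character(gids[mm$matches$gt[r]])
        p <- pids[mm$matches$pred[r]]
        lp <- last_match[[g]]
        if (!is.null(lp) && lp != p) idsw <- idsw + 1L
        last_match[[g]] <- p
      }
    }
  }
  n_gt <- nrow(gt)
  list(MOTA = (1 - (fn + fp + idsw) / n_gt) * 100,
       MOTP = if (tp > 0) iou_sum / tp * 100 else NA_real_,
       IDs = idsw, FP = fp, FN = fn, TP = tp, n_gt = n_gt)
}

# overlap counts: frames where gt id g and pred id p co-occur with IoU >= thr
pair_overlaps <- function(gt, pred, thr, one_to_one = FALSE) {
  gids <- sort(unique(gt$id)); pids <- sort(unique(pred$id))
  ov <- matrix(0L, length(gids), length(pids),
               dimnames = list(gids, pids))
  gtf <- split_frames(gt); prf <- split_frames(pred)
  for (f in intersect(names(gtf), names(prf))) {
    gi <- gtf[[f]]; pi <- prf[[f]]
    ious <- iou_matrix(traj_boxes(gt[gi, , drop = FALSE]),
                       traj_boxes(pred[pi, , drop = FALSE]))
    hit <- which(ious >= thr, arr.ind = TRUE)
    if (nrow(hit)) {
      gi2 <- match(gt$id[gi[hit[, 1]]], gids)
      pi2 <- match(pred$id[pi[hit[, 2]]], pids)
      for (r in seq_along(gi2))
        ov[gi2[r], pi2[r]] <- ov[gi2[r], pi2[r]] + 1L
    }
  }
  list(ov = ov, gids = gids, pids = pids,
       n_g = as.integer(table(factor(gt$id, levels = gids))),
       n_p = as.integer(table(factor(pred$id, levels = pids))))
}

#' IDF1: identity-preservation F1 score
#'
#' An optimal global bijection between ground-truth and predicted
#' identities (assignment problem over per-pair co-occurrence counts at IoU
#' at least `alpha`) defines IDTP; then
#' `IDF1 = 2 IDTP / (2 IDTP + IDFP + IDFN) * 100`.
#'
#' @inheritParams mota_motp
#' @return IDF1 in `[0, 100]`.
#' @export
idf1 <- function(gt, pred, cfg = eval_config()) {
  if (nrow(pred) == 0L) return(0)
  po <- pair_overlaps(gt, pred, cfg$alpha)
  sol <- solve_assignment(-po$ov)
  idtp <- sum(po$ov[cbind(sol$rows, sol$cols)])
  idfn <- nrow(gt) - idtp
  idfp <- nrow(pred) - idtp
  2 * idtp / (2 * idtp + idfp + idfn) * 100
}

#' HOTA: higher-order tracking accuracy
#'
#' For each localisation threshold `alpha` in the grid: detections and
#' truths are matched one-to-one per frame (Hungarian, preferring pairs
#' whose trajectories align globally, gated at IoU >= alpha), giving
#' `DetA(alpha) = TP / (TP + FN + FP)`; each TP `c = (g, p)` carries an
#' association score `A(c) = TPA / (TPA + FNA + FPA)` over the paired
#' trajectories, and `AssA(alpha)` is the mean of `A(c)` over TPs
#' (`AssR` uses `TPA / (TPA + FNA)`). `HOTA(alpha) =
#' sqrt(DetA(alpha) * AssA(alpha))`; the reported score averages over the
#' grid and is expressed as a percentage.
#'
#' @inheritParams mota_motp
#' @return A list with `HOTA`, `DetA`, `AssA`, `AssR` (percentages averaged
#'   over the grid) and `per_alpha`, a `data.frame(alpha, HOTA, DetA, AssA,
#'   AssR)` of the per-threshold values (as fractions in `[0, 1]`).
#' @export
hota <- function(gt, pred, cfg = eval_config()) {
  alphas <- cfg$hota_alphas
  gtf <- split_frames(gt); prf <- split_frames(pred)
  frames <- sort(unique(c(gt$frame, pred$frame)))
  per <- lapply(alphas, function(a) {
    gids <- sort(unique(gt$id)); pids <- sort(unique(pred$id))
    if (!length(pids))
      return(c(HOTA = 0, DetA = 0, AssA = 0, AssR = 0))
    # pass 1: potential alignment of each (gt id, pred id) pair
    pot <- matrix(0L, length(gids), length(pids))
    for (f in frames) {
      gi <- gtf[[as.character(f)]] %||% integer(0)
      pi <- prf[[as.character(f)]] %||% integer(0)
      if (!length(gi) || !length(pi)) next
      ious <- iou_matrix(traj_boxes(gt[gi, , drop = FALSE]),
                         traj_boxes(pred[pi, , drop = FALSE]))
      hit <- which(ious >= a, arr.ind = TRUE)
      if (nrow(hit)) {
        r1 <- match(gt$id[gi[hit[, 1]]], gids)
        r2 <- match(pred$id[pi[hit[, 2]]], pids)
        for (r in seq_along(r1)) pot[r1[r], r2[r]] <- pot[r1[r], r2[r]] + 1L
      }
    }
    n_g <- as.integer(table(factor(gt$id, levels = gids)))
    n_p <- as.integer(table(factor(pred$id, levels = pids)))
    align <- pot / (outer(n_g, n_p, "+") - pot)
    # pass 2: per-frame matching preferring globally aligned pairs
    mc <- matrix(0L, length(gids), length(pids))
    tp <- 0L; fn <- 0L; fp <- 0L
    for (f in frames) {
      gi <- gtf[[as.character(f)]] %||% integer(0)
      pi <- prf[[as.character(f)]] %||% integer(0)
      if (!length(gi)) { fp <- fp + length(pi); next }
      if (!length(pi)) { fn <- fn + length(gi); next }
      ious <- iou_matrix(traj_boxes(gt[gi, , drop = FALSE]),
                         traj_boxes(pred[pi, , drop = FALSE]))
      score <- align[match(gt$id[gi], gids), match(pred$id[pi], pids),
                     drop = FALSE] + ious * 1e-6
      cost <- max(score) + 1 - score
      cost[ious < a] <- Inf
      sol <- solve_assignment(cost)
      tp <- tp + length(sol$rows)
      fn <- fn + length(gi) - length(sol$rows)
      fp <- fp + length(pi) - length(sol$rows)
      if (length(sol$rows)) {
        r1 <- match(gt$id[gi[sol$rows]], gids)
        r2 <- match(pred$id[pi[sol$cols]], pids)
        for (r in seq_along(r1)) mc[r1[r], r2[r]] <- mc[r1[r], r2[r]] + 1L
      }
    }
    if (tp + fn + fp == 0L)
      return(c(HOTA = 0, DetA = 0, AssA = 0, AssR = 0))
    deta <- tp / (tp + fn + fp)
    if (tp == 0L)
      return(c(HOTA = 0, DetA = deta, AssA = 0, AssR = 0))
    assa_sum <- 0; assr_sum <- 0
    for (i in seq_along(gids)) for (j in seq_along(pids)) {
      if (mc[i, j] > 0L) {
        tpa <- mc[i, j]
        fna <- n_g[i] - tpa
        fpa <- n_p[j] - tpa
        assa_sum <- assa_sum + tpa * tpa / (tpa + fna + fpa)
        assr_sum <- assr_sum + tpa * tpa / (tpa + fna)
      }
    }
    assa <- assa_sum / tp
    assr <- assr_sum / tp
    c(HOTA = sqrt(deta * assa), DetA = deta, AssA = assa, AssR = assr)
  })
  tab <- do.call(rbind, per)
  per_alpha <- data.frame(alpha = alphas, HOTA = tab[, "HOTA"],
                          DetA = tab[, "DetA"], AssA = tab[, "AssA"],
                          AssR = tab[, "AssR"])
  list(HOTA = mean(tab[, "HOTA"]) * 100, DetA = mean(tab[, "DetA"]) * 100,
       AssA = mean(tab[, "AssA"]) * 100, AssR = mean(tab[, "AssR"]) * 100,
       per_alpha = per_alpha)
}

#' Full tracking evaluation report
#'
#' Runs the CLEAR metrics, IDF1 and HOTA on a ground-truth/prediction pair
#' of trajectory sets and collects every metric with its intermediate
#' counts.
#'
#' @inheritParams mota_motp
#' @return A list of class `"evaluation_report"`.
#' @export
evaluate_tracking <- function(gt, pred, cfg = eval_config()) {
  cm <- mota_motp(gt, pred, cfg)
  h <- hota(gt, pred, cfg)
  structure(list(
    MOTA = cm$MOTA, MOTP = cm$MOTP, IDF1 = idf1(gt, pred, cfg),
    HOTA = h$HOTA, DetA = h$DetA, AssA = h$AssA, AssR = h$AssR,
    IDs = cm$IDs, FP = cm$FP, FN = cm$FN, TP = cm$TP, n_gt = cm$n_gt,
    per_alpha = h$per_alpha, alpha = cfg$alpha
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(paste0("tracking evaluation (alpha = %.2f)\n",
                     "  MOTA %.3f  MOTP %.3f  IDF1 %.3f\n",
                     "  HOTA %.3f  DetA %.3f  AssA %.3f  AssR %.3f\n",
                     "  IDs %d  FP %d  FN %d  TP %d  (n_gt %d)\n"),
              x$alpha, x$MOTA, x$MOTP, x$IDF1, x$HOTA, x$DetA, x$AssA,
              x$AssR, x$IDs, x$FP, x$FN, x$TP, x$n_gt))
  invisible(x)
}
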