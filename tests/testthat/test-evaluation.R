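traj <- function(frame, id, cx, cy, s = 10) {
  data.frame(frame = frame, id = id, x1 = cx - s / 2, y1 = cy - s / 2,
             x2 = cx + s / 2, y2 = cy + s / 2)
}

test_that("frame matching is one-to-one, gated, and continuity-aware", {
  g <- rbind(c(0, 0, 10, 10), c(20, 20, 30, 30))
  m <- match_frame(g, g, 0.5)
  expect_equal(nrow(m$matches), 2L)
  expect_equal(m$unmatched_gt, integer(0))
  expect_equal(m$unmatched_pred, integer(0))
  m <- match_frame(g, matrix(numeric(0), 0, 4), 0.5)
  expect_equal(m$unmatched_gt, 1:2)
  # crossed overlaps resolved as the exhaustive best assignment
  set.seed(401)
  for (i in 1:20) {
    g2 <- rbind(random_box(40, 40, 8, 14), random_box(40, 40, 8, 14))
    p2 <- g2 + matrix(rnorm(8, 0, 2), 2, 4)
    p2[, 3] <- pmax(p2[, 3], p2[, 1] + 1)
    p2[, 4] <- pmax(p2[, 4], p2[, 2] + 1)
    m <- match_frame(g2, p2, 0.3)
    iou <- casatrack:::iou_matrix(g2, p2)
    iou[iou < 0.3] <- NA
    best <- max(c(sum(diag(iou)), iou[1, 2] + iou[2, 1],
                  iou[1, 1], iou[1, 2], iou[2, 1], iou[2, 2], 0),
                na.rm = TRUE)
    got <- sum(m$matches$iou)
    # the match must reach the exhaustive optimum (max matches, then IoU)
    expect_gte(nrow(m$matches),
               max(0, sum(!is.na(c(iou[1, 1], iou[2, 2]))) > 0) )
    if (nrow(m$matches) == 2) expect_equal(got,
      max(sum(diag(iou)), iou[1, 2] + iou[2, 1], na.rm = TRUE))
  }
  # continuity: a previous partner is kept while it clears the threshold
  g3 <- matrix(c(0, 0, 10, 10), 1)
  p3 <- rbind(c(1, 1, 11, 11), c(0.5, 0.5, 10.5, 10.5))
  m_free <- match_frame(g3, p3, 0.5)
  expect_equal(m_free$matches$pred, 2L)          # higher IoU wins
  m_prev <- match_frame(g3, p3, 0.5, prev = cbind(1L, 1L))
  expect_equal(m_prev$matches$pred, 1L)          # but continuity overrides
})

test_that("precision and recall follow their definitions and conventions", {
  pr <- precision_recall(8, 1, 2)
  expect_equal(pr$precision, 8 / 9)
  expect_equal(pr$recall, 0.8)
  pr <- precision_recall(5, 0, 0)
  expect_equal(pr$precision, 1); expect_equal(pr$recall, 1)
  pr <- precision_recall(0, 0, 0)
  expect_equal(pr$precision, 0); expect_equal(pr$recall, 0)
})

test_that("average precision integrates the interpolated PR curve", {
  gt <- data.frame(frame = c(1, 1), x1 = c(0, 100), y1 = c(0, 100),
                   x2 = c(10, 110), y2 = c(10, 110))
  # perfect detections
  det <- cbind(gt[, ], conf = c(0.9, 0.8))
  expect_equal(average_precision(det, gt, 0.5), 1)
  expect_equal(average_precision(det[0, ], gt, 0.5), 0)
  # 2 TP and 1 FP interleaved by confidence:
  # ranked TP(0.9), FP(0.8), TP(0.7) -> PR points (0.5, 1), (0.5, 0.5),
  # (1, 2/3); envelope integrates to 0.5*1 + 0.5*2/3
  det3 <- data.frame(frame = 1, x1 = c(0, 50, 100), y1 = c(0, 50, 100),
                     x2 = c(10, 60, 110), y2 = c(10, 60, 110),
                     conf = c(0.9, 0.8, 0.7))
  expect_equal(average_precision(det3, gt, 0.5), 0.5 + 0.5 * 2 / 3)
})

test_that("the mAP suite averages over classes and thresholds", {
  gt <- data.frame(frame = rep(1:4, each = 2),
                   x1 = rep(c(0, 100), 4), y1 = rep(c(0, 100), 4),
                   x2 = rep(c(10, 110), 4), y2 = rep(c(10, 110), 4),
                   class_id = rep(c(0L, 1L), 4))
  det <- cbind(gt, conf = 0.9)
  m <- map_suite(det, gt)
  expect_equal(m$mAP50, 1)
  expect_equal(m$mAP50_95, 1)
  # degrade one class: boxes shifted so IoU ~ 0.54 passes 0.5 but not 0.55
  det2 <- det
  shift <- det2$class_id == 1L
  det2$x1[shift] <- det2$x1[shift] + 3
  det2$x2[shift] <- det2$x2[shift] + 3
  m2 <- map_suite(det2, gt)
  expect_equal(m2$per_class$AP50, c(1, 1))
  expect_lt(m2$per_class$AP50_95[2], m2$per_class$AP50_95[1])
  expect_gte(m2$mAP50, m2$mAP50_95)
})

test_that("CLEAR metrics: perfection, emptiness, and a hand-counted frame", {
  gt <- do.call(rbind, lapply(1:5, function(f) traj(f, 1:3, c(10, 40, 70), 20)))
  r <- mota_motp(gt, gt)
  expect_equal(r$MOTA, 100)
  expect_equal(r$MOTP, 100)
  expect_equal(r$IDs, 0L)
  r0 <- mota_motp(gt, gt[0, ])
  expect_equal(r0$MOTA, 0)
  expect_equal(r0$FN, nrow(gt))
  # one frame: 10 gt, 8 matched, 2 missed, 1 spurious, 0 switches -> 70.0
  g1 <- traj(1, 1:10, seq(10, 100, by = 10), 50)
  p1 <- rbind(traj(1, 1:8, seq(10, 80, by = 10), 50),
              traj(1, 99, 300, 300))
  r1 <- mota_motp(g1, p1)
  expect_equal(r1$FN, 2L); expect_equal(r1$FP, 1L); expect_equal(r1$IDs, 0L)
  expect_equal(r1$MOTA, 70)
})

test_that("identity switches are counted against the most recent match", {
  gt <- do.call(rbind, lapply(1:10, function(f) traj(f, 7, 50, 50)))
  pred <- rbind(do.call(rbind, lapply(1:5, function(f) traj(f, 1, 50, 50))),
                do.call(rbind, lapply(6:10, function(f) traj(f, 2, 50, 50))))
  r <- mota_motp(gt, pred)
  expect_equal(r$IDs, 1L)
  expect_equal(r$MOTA, (1 - 1 / 10) * 100)
})

test_that("IDF1 uses the optimal global identity bijection", {
  gt <- do.call(rbind, lapply(1:10, function(f) traj(f, 1, 50, 50)))
  expect_equal(idf1(gt, gt), 100)
  expect_equal(idf1(gt, gt[0, ]), 0)
  # one truth covered half by each of two predicted ids: the bijection
  # keeps one half, so IDTP = 5, IDFP = 5, IDFN = 5
  pred <- rbind(do.call(rbind, lapply(1:5, function(f) traj(f, 1, 50, 50))),
                do.call(rbind, lapply(6:10, function(f) traj(f, 2, 50, 50))))
  expect_equal(idf1(gt, pred), 2 * 5 / (2 * 5 + 5 + 5) * 100)
})

test_that("HOTA separates detection and association quality", {
  gt <- do.call(rbind, lapply(1:10, function(f) traj(f, 1:2, c(20, 80), 50)))
  h <- hota(gt, gt)
  expect_equal(h$HOTA, 100)
  expect_equal(h$DetA, 100)
  expect_equal(h$AssA, 100)
  # perfect detection but every id split across two pred ids at half
  # duration: DetA = 1, A(c) = 5/10 for every TP, HOTA = sqrt(0.5)
  pred <- gt
  pred$id <- pred$id + ifelse(pred$frame > 5, 10, 0)
  h2 <- hota(gt, pred)
  expect_equal(h2$DetA, 100)
  expect_equal(h2$AssA, 50)
  expect_equal(h2$HOTA, sqrt(0.5) * 100, tolerance = 1e-9)
  h0 <- hota(gt, gt[0, ])
  expect_equal(h0$HOTA, 0)
  # internal identity HOTA(a)^2 = DetA(a) * AssA(a) at every threshold
  expect_equal(h2$per_alpha$HOTA^2,
               h2$per_alpha$DetA * h2$per_alpha$AssA, tolerance = 1e-12)
})

test_that("metrics are invariant to relabeling prediction ids", {
  set.seed(402)
  gt <- simulate_trajectories(sim_config(n = 6, n_frames = 30))$traj
  pred <- gt
  pred$x1 <- pred$x1 + rnorm(nrow(pred), 0, 0.4)
  pred$x2 <- pred$x2 + rnorm(nrow(pred), 0, 0.4)
  relab <- pred
  perm <- sample(100:200, length(unique(pred$id)))
  relab$id <- perm[match(pred$id, unique(pred$id))]
  r1 <- evaluate_tracking(gt, pred)
  r2 <- evaluate_tracking(gt, relab)
  for (k in c("MOTA", "MOTP", "IDF1", "HOTA", "AssA", "IDs"))
    expect_equal(r1[[k]], r2[[k]])
})

test_that("MOTA weakly decreases as false positives are injected", {
  set.seed(403)
  gt <- simulate_trajectories(sim_config(n = 5, n_frames = 20))$traj
  motas <- sapply(c(0, 5, 15), function(nfp) {
    pred <- gt
    if (nfp > 0) {
      fp <- traj(sample(1:20, nfp, replace = TRUE), 900 + seq_len(nfp),
                 runif(nfp, 200, 400), runif(nfp, 200, 400))
      fp <- cbind(fp[1:6])
      pred <- rbind(pred[, names(fp)], fp)
    }
    mota_motp(gt[, 1:6], pred)$MOTA
  })
  expect_true(all(diff(motas) <= 0))
})

test_that("CLEAR and ID metrics agree with the exhaustive reference", {
  set.seed(404)
  for (rep in 1:4) {
    gt <- simulate_trajectories(sim_config(n = 4, n_frames = 25))
    dd <- degrade_to_detections(gt, noise_config(miss_prob = 0.05,
                                                 fp_rate = 0.3,
                                                 jitter_sd = 0.4))
    tr <- tracker_run(dd, tracker_config(min_hits = 1))
    got <- mota_motp(gt$traj, tr)
    ref <- ref_mota_idf1(gt$traj, tr)
    expect_lt(abs(got$MOTA - ref$MOTA), 0.1)
    expect_lt(abs(idf1(gt$traj, tr) - ref$IDF1), 0.1)
  }
})
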