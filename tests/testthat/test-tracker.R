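det_at <- function(cx, cy, s = 16, conf = 1, emb = NULL, class_id = 0L)
  detection(c(cx - s / 2, cy - s / 2, cx + s / 2, cy + s / 2),
            class_id = class_id, conf = conf, embedding = emb)

test_that("track initialisation centres the state with zero velocity", {
  d <- detection(c(10, 10, 16, 16))
  t <- kalman_init(d)
  expect_equal(t$mean[1:2], c(13, 13))
  expect_equal(t$mean[3:4], c(6, 6))
  expect_equal(t$mean[5:8], rep(0, 4))
  expect_equal(t$status, "tentative")
  t2 <- kalman_init(d)
  expect_false(t$id == t2$id)
  # covariance positive definite in the dynamic subspace
  ev <- eigen(t$cov[1:6, 1:6], symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
})

test_that("prediction advances by the velocity and inflates uncertainty", {
  t <- kalman_init(detection(c(10, 10, 16, 16)))
  t0 <- kalman_predict(t)
  expect_equal(t0$mean[1:2], c(13, 13))    # zero velocity: position fixed
  t$mean[5:6] <- c(2, 0)
  tk <- t
  for (k in 1:5) tk <- kalman_predict(tk)
  expect_equal(tk$mean[1], 13 + 2 * 5)     # linear recurrence, 2 px/frame
  expect_equal(tk$mean[2], 13)
  expect_equal(tk$time_since_update, 5L)
  expect_gt(tk$cov[1, 1], t$cov[1, 1])
})

test_that("the update is the textbook gain-weighted correction", {
  t <- kalman_init(detection(c(10, 10, 16, 16)))
  t <- kalman_predict(t)
  # measurement equal to the prediction leaves the mean unchanged
  t_same <- kalman_update(t, detection(c(10, 10, 16, 16), conf = 0.5))
  expect_equal(t_same$mean[1:4], c(13, 13, 6, 6), tolerance = 1e-9)
  # random case against the standard equations evaluated independently
  set.seed(301)
  t <- kalman_init(detection(c(10, 10, 16, 16)))
  t$mean[5:6] <- c(1, -0.5)
  t <- kalman_predict(t)
  d <- detection(c(11.3, 9.1, 17.7, 15.9), conf = 0.4)
  z <- c((11.3 + 17.7) / 2, (9.1 + 15.9) / 2, 6.4, 6.8)
  H <- cbind(diag(4), matrix(0, 4, 4))
  R <- casatrack:::kf_R((6.4 + 6.8) / 2, 0.4)
  S <- H %*% t$cov %*% t(H) + R
  K <- t$cov %*% t(H) %*% solve(S)
  expected_mean <- t$mean + as.numeric(K %*% (z - H %*% t$mean))
  upd <- kalman_update(t, d)
  expect_equal(upd$mean, expected_mean, tolerance = 1e-9)
  expect_equal(upd$time_since_update, 0L)
  # posterior trace does not grow in the measured subspace
  expect_lte(sum(diag(upd$cov[1:4, 1:4])), sum(diag(t$cov[1:4, 1:4])))
  # vanishing measurement noise (confidence 1): posterior = measurement
  t1 <- kalman_init(detection(c(0, 0, 6, 6)))
  t1 <- kalman_predict(t1)
  exact <- kalman_update(t1, detection(c(4, 4, 10, 10), conf = 1))
  expect_equal(exact$mean[1:4], c(7, 7, 6, 6), tolerance = 1e-9)
})

test_that("appearance smoothing follows the confidence-driven rate", {
  cfg <- tracker_config()
  e1 <- c(1, 0, 0, 0); e2 <- c(0, 1, 0, 0)
  t <- kalman_init(detection(c(0, 0, 6, 6), embedding = e1))
  # below the band: alpha = alpha_max
  d <- detection(c(0, 0, 6, 6), conf = cfg$conf_low / 2, embedding = e2)
  got <- appearance_update(t, d, cfg)
  want <- cfg$alpha_max * e1 + (1 - cfg$alpha_max) * e2
  expect_equal(got, want / sqrt(sum(want^2)))
  # above the band: alpha = alpha_min
  d <- detection(c(0, 0, 6, 6), conf = 0.99, embedding = e2)
  got <- appearance_update(t, d, cfg)
  want <- cfg$alpha_min * e1 + (1 - cfg$alpha_min) * e2
  expect_equal(got, want / sqrt(sum(want^2)))
  # identical embeddings are a fixed point
  d <- detection(c(0, 0, 6, 6), conf = 0.5, embedding = e1)
  expect_equal(appearance_update(t, d, cfg), e1)
  # a detection without an embedding leaves the track embedding alone
  d <- detection(c(0, 0, 6, 6), conf = 0.5)
  expect_equal(appearance_update(t, d, cfg), e1)
})

test_that("association cost blends motion and appearance as specified", {
  # identical box and embedding: zero cost
  e <- c(1, 0, 0, 0)
  t <- kalman_init(detection(c(0, 0, 6, 6), embedding = e))
  cfg <- tracker_config()
  cost <- association_cost(list(t), list(detection(c(0, 0, 6, 6), conf = 1,
                                                   embedding = e)), cfg)
  expect_equal(cost[1, 1], 0)
  # disjoint box, orthogonal embedding, w = 0.5:
  # 0.5 * 1 + 0.5 * 0.5 = 0.75 (gates opened to observe the raw blend)
  cfg5 <- tracker_config(gate = 1, motion_gate = 1,
                         w_app_min = 0.5, w_app_max = 0.5)
  d <- detection(c(100, 100, 106, 106), conf = 1,
                 embedding = c(0, 1, 0, 0))
  cost <- association_cost(list(t), list(d), cfg5)
  expect_equal(cost[1, 1], 0.75)
  # w_app = 0: pure motion cost
  cfg0 <- tracker_config(gate = 1, motion_gate = 1,
                         w_app_min = 0, w_app_max = 0)
  cost <- association_cost(list(t), list(d), cfg0)
  expect_equal(cost[1, 1], 1)
  # mismatched embedding dimensions are an error
  d_bad <- detection(c(0, 0, 6, 6), embedding = c(1, 0))
  expect_error(association_cost(list(t), list(d_bad), cfg), "dimension")
  # the gating cascade forbids appearance-only long jumps
  cost <- association_cost(list(t), list(detection(c(100, 100, 106, 106),
                                                   conf = 1, embedding = e)),
                           cfg)
  expect_identical(cost[1, 1], Inf)
})

test_that("assignment is one-to-one, gated, and optimal", {
  a <- associate(matrix(0.2, 1, 1), gate = 0.7)
  expect_equal(nrow(a$matches), 1L)
  a <- associate(matrix(c(Inf, Inf), 1, 2), gate = 0.7)
  expect_equal(nrow(a$matches), 0L)
  expect_equal(a$unmatched_detections, 1:2)
  set.seed(302)
  for (i in 1:30) {
    cost <- matrix(runif(9), 3, 3)
    a <- associate(cost, gate = Inf)
    expect_equal(sum(cost[a$matches]), brute_assignment(cost)$cost)
    expect_equal(anyDuplicated(a$matches[, 1]), 0L)
    expect_equal(anyDuplicated(a$matches[, 2]), 0L)
  }
})

test_that("a single well-detected target keeps one id for its whole life", {
  frames <- lapply(1:30, function(f) list(det_at(10 + 2 * f, 50)))
  tr <- tracker_run(frames, tracker_config(min_hits = 1))
  expect_equal(length(unique(tr$id)), 1L)
  expect_equal(nrow(tr), 30L)
  expect_true(all(diff(tr$frame) == 1))
})

test_that("a track outliving max_age dies; reappearance takes a fresh id", {
  cfg <- tracker_config(min_hits = 1, max_age = 5)
  frames <- c(lapply(1:10, function(f) list(det_at(50, 50))),
              lapply(11:17, function(f) list()),          # 7 > max_age
              lapply(18:24, function(f) list(det_at(50, 50))))
  tr <- tracker_run(frames, cfg)
  ids <- unique(tr$id)
  expect_length(ids, 2L)
  expect_true(all(tr$id[tr$frame <= 10] == ids[1]))
  expect_true(all(tr$id[tr$frame >= 18] == ids[2]))
})

test_that("a short occlusion is bridged by observation-centric recovery", {
  cfg <- tracker_config(min_hits = 1, max_age = 10)
  mk <- function(f) list(det_at(10 + 3 * f, 50))
  frames <- c(lapply(1:10, mk), lapply(11:13, function(f) list()),
              lapply(14:20, mk))
  tr <- tracker_run(frames, cfg)
  expect_length(unique(tr$id), 1L)
  expect_false(any(tr$frame %in% 11:13))
})

test_that("appearance cues prevent identity swaps when two targets bounce", {
  # two targets approach head-on, meet at x = 50, and both reverse; a pure
  # constant-velocity association follows the crossing straight through and
  # swaps identities, while orthogonal appearance embeddings disambiguate
  eA <- c(1, 0, 0, 0, 0, 0, 0, 0); eB <- c(0, 1, 0, 0, 0, 0, 0, 0)
  pos <- function(f) {
    xa <- if (f <= 13) 2 + 4 * f else 54 - 4 * (f - 13)
    xb <- if (f <= 13) 102 - 4 * f else 50 + 4 * (f - 13)
    c(xa, xb)
  }
  frames_app <- lapply(1:26, function(f) {
    p <- pos(f)
    list(det_at(p[1], 50, emb = eA), det_at(p[2], 50, emb = eB))
  })
  frames_noapp <- lapply(1:26, function(f) {
    p <- pos(f)
    list(det_at(p[1], 50), det_at(p[2], 50))
  })
  id_of_targetA <- function(tr) {
    # the track reporting near x = 2 + 4 at frame 1 vs near x = 2 at frame 26
    first <- tr[tr$frame == 1, ]; last <- tr[tr$frame == 26, ]
    a0 <- first$id[which.min(abs((first$x1 + first$x2) / 2 - 6))]
    a1 <- last$id[which.min(abs((last$x1 + last$x2) / 2 - 2))]
    c(a0, a1)
  }
  cfg_app <- tracker_config(min_hits = 1, w_app_min = 0.75, w_app_max = 0.75)
  tr_app <- tracker_run(frames_app, cfg_app)
  ids <- id_of_targetA(tr_app)
  expect_equal(ids[1], ids[2])      # appearance keeps identity across bounce
  cfg_no <- tracker_config(min_hits = 1, w_app_min = 0, w_app_max = 0)
  tr_no <- tracker_run(frames_noapp, cfg_no)
  ids_no <- id_of_targetA(tr_no)
  expect_false(ids_no[1] == ids_no[2])   # motion-only follows straight lines
})

test_that("tracker output is deterministic, dense-id, and one-per-frame", {
  set.seed(303)
  gt <- simulate_trajectories(sim_config(n = 12, n_frames = 60))
  dets <- degrade_to_detections(gt, noise_config(miss_prob = 0.05,
                                                 fp_rate = 2, jitter_sd = 0.5))
  tr1 <- tracker_run(dets, tracker_config())
  tr2 <- tracker_run(dets, tracker_config())
  expect_identical(tr1, tr2)
  expect_equal(nrow(unique(tr1[, c("frame", "id")])), nrow(tr1))
  for (id in unique(tr1$id))
    expect_true(all(diff(tr1$frame[tr1$id == id]) >= 1))
  expect_true(all(tr1$id >= 1))
  expect_equal(tracker_run(list(), tracker_config()),
               tracker_run(list(), tracker_config()))
  expect_equal(nrow(tracker_run(list(), tracker_config())), 0L)
})

test_that("frames must be presented in increasing order", {
  st <- tracker_state(tracker_config())
  st <- tracker_step(st, list(det_at(10, 10)), 1)
  expect_error(tracker_step(st, list(det_at(10, 10)), 1), "increasing")
})

test_that("camera-motion compensation cancels a synthetic global drift", {
  set.seed(304)
  gt <- simulate_trajectories(sim_config(n = 8, n_frames = 40))
  dets <- degrade_to_detections(gt, noise_config_clean())
  offsets <- cbind(cumsum(rnorm(40, 0, 3)), cumsum(rnorm(40, 0, 3)))
  drift <- dets
  drift$detections$x1 <- drift$detections$x1 + offsets[drift$detections$frame, 1]
  drift$detections$x2 <- drift$detections$x2 + offsets[drift$detections$frame, 1]
  drift$detections$y1 <- drift$detections$y1 + offsets[drift$detections$frame, 2]
  drift$detections$y2 <- drift$detections$y2 + offsets[drift$detections$frame, 2]
  cmc <- function(frame, boxes) {
    prev <- if (frame > 1) offsets[frame - 1, ] else c(0, 0)
    step <- offsets[frame, ] - prev
    boxes + matrix(rep(step, each = nrow(boxes)), nrow(boxes), 4)[, c(1, 2, 1, 2)]
  }
  base <- tracker_run(dets, tracker_config())
  comp <- tracker_run(drift, tracker_config(cmc = cmc))
  expect_equal(comp$id, base$id)
  expect_equal(comp$x1 - offsets[comp$frame, 1], base$x1, tolerance = 1e-9)
  expect_equal(comp$y2 - offsets[comp$frame, 2], base$y2, tolerance = 1e-9)
})

test_that("a track's class is the majority class of its detections", {
  frames <- lapply(1:9, function(f)
    list(det_at(50, 50, class_id = if (f %% 3 == 0) 1L else 0L)))
  tr <- tracker_run(frames, tracker_config(min_hits = 1))
  expect_equal(unname(casatrack:::track_class(
    list(class_votes = c(6L, 3L, 0L)))), 0L)
  expect_true(all(tr$class_id %in% c(0L, 1L)))
})
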