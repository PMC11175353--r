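#' Tracker configuration
#'
#' Defaults are chosen for 25-30 fps microscopy clips of progressively
#' motile sperm: a track survives about one second without support
#' (`max_age = 30`), needs three hits to be trusted (`min_hits = 3`), and
#' association blends motion with appearance, trusting appearance more for
#' confident detections.
#'
#' @param gate Association costs above this are forbidden (default 0.7).
#' @param motion_gate Pairs whose motion cost alone exceeds this are
#'   forbidden regardless of appearance (default 0.95, i.e. a track may
#'   never follow appearance to a detection its motion model rules out —
#'   the standard gating cascade).
#' @param bootstrap_gate Gate on the NWD motion cost of the second
#'   association stage (default 0.5). The second stage exists to bootstrap
#'   young tracks without velocity estimates across one-frame displacements
#'   of a few pixels; a tight gate keeps coasting tracks from latching onto
#'   distant spurious detections.
#' @param w_app_min,w_app_max Appearance weight bounds; the blend weight is
#'   `w_app_min + (w_app_max - w_app_min) * trust(conf)`.
#' @param alpha_min,alpha_max Embedding-smoothing bounds: high-confidence
#'   detections update the track embedding faster (smaller alpha).
#' @param conf_low,conf_high Confidence band mapping detection confidence to
#'   trust in `[0, 1]` by linear clamping.
#' @param max_age Frames a track may coast unmatched before dying.
#' @param min_hits Hits required to confirm a track. Tentative-phase
#'   observations are buffered and emitted retroactively on confirmation.
#' @param motion_metric `"iou"` (default) or `"nwd"` for the motion cost.
#' @param nwd_constant Constant for the NWD motion cost.
#' @param cmc Optional camera-motion compensation: a function
#'   `(frame, boxes)` returning the warped `n x 4` box matrix. `NULL` means
#'   the identity (static microscope stage).
#' @return A list of class `"tracker_config"`.
#' @export
tracker_config <- function(gate = 0.7, motion_gate = 0.95,
                           bootstrap_gate = 0.5,
                           w_app_min = 0.25, w_app_max = 0.75,
                           alpha_min = 0.8, alpha_max = 0.95,
                           conf_low = 0.1, conf_high = 0.6,
                           max_age = 30L, min_hits = 3L,
                           motion_metric = c("iou", "nwd"),
                           nwd_constant = 12.8, cmc = NULL) {
  motion_metric <- match.arg(motion_metric)
  stopifnot(w_app_min >= 0, w_app_min <= w_app_max, w_app_max <= 1,
            alpha_min > 0, alpha_min <= alpha_max, alpha_max < 1,
            conf_low < conf_high, max_age >= 1, min_hits >= 1)
  structure(list(gate = gate, motion_gate = motion_gate,
                 bootstrap_gate = bootstrap_gate,
                 w_app_min = w_app_min, w_app_max = w_app_max,
                 alpha_min = alpha_min, alpha_max = alpha_max,
                 conf_low = conf_low, conf_high = conf_high,
                 max_age = as.integer(max_age), min_hits = as.integer(min_hits),
                 motion_metric = motion_metric, nwd_constant = nwd_constant,
                 cmc = cmc),
            class = "tracker_config")
}

trust_of <- function(conf, cfg) {
  pmin(pmax((conf - cfg$conf_low) / (cfg$conf_high - cfg$conf_low), 0), 1)
}

#' Blend a track's appearance embedding with a matched detection's
#'
#' Exponential smoothing with a confidence-driven rate:
#' `trust = clamp((conf - conf_low) / (conf_high - conf_low), 0, 1)`,
#' `alpha = alpha_max - (alpha_max - alpha_min) * trust`, and the new
#' embedding is the renormalised mix `alpha * e_track + (1 - alpha) * e_det`.
#' Confident detections therefore refresh the stored appearance faster,
#' while low-quality (blurred, occluded) ones barely perturb it. A missing
#' detection embedding leaves the track embedding unchanged.
#'
#' @param t A `"track_state"`.
#' @param d The matched [detection()].
#' @param cfg A [tracker_config()].
#' @return The updated embedding (unit norm), or the track's previous one.
#' @export
appearance_update <- function(t, d, cfg) {
  if (is.null(d$embedding)) return(t$embedding)
  if (is.null(t$embedding)) return(d$embedding)
  trust <- trust_of(d$conf, cfg)
  alpha <- cfg$alpha_max - (cfg$alpha_max - cfg$alpha_min) * trust
  e <- alpha * t$embedding + (1 - alpha) * d$embedding
  e / sqrt(sum(e^2))
}

#' Blended motion/appearance association cost matrix
#'
#' `C[i, j] = (1 - w_j) * motion_cost(i, j) + w_j * appearance_cost(i, j)`
#' with `motion_cost = 1 - IoU` between the track's predicted box and the
#' detection (or `1 - NWD` when configured), `appearance_cost =
#' (1 - cosine) / 2`, and the appearance weight `w_j` growing linearly with
#' the detection's trust from `w_app_min` to `w_app_max`. Pairs whose cost
#' exceeds the gate are marked forbidden (`Inf`). When either side lacks an
#' embedding the cost for that pair is pure motion.
#'
#' @param tracks List of `"track_state"` objects (already predicted).
#' @param detections List of [detection()] objects.
#' @param cfg A [tracker_config()].
#' @param predicted_boxes Optional `n x 4` matrix of (possibly
#'   motion-compensated) predicted boxes overriding the tracks' own.
#' @return An `n_tracks x n_detections` matrix with `Inf` for gated pairs.
#' @export
association_cost <- function(tracks, detections, cfg,
                             predicted_boxes = NULL) {
  n <- length(tracks); m <- length(detections)
  if (n == 0L || m == 0L) return(matrix(numeric(0), n, m))
  TB <- if (is.null(predicted_boxes))
    do.call(rbind, lapply(tracks, track_predicted_box)) else predicted_boxes
  DB <- do.call(rbind, lapply(detections, function(d) d$box))
  motion <- if (cfg$motion_metric == "nwd")
    1 - nwd_matrix(TB, DB, cfg$nwd_constant) else 1 - iou_matrix(TB, DB)

  emb_t <- lapply(tracks, function(t) t$embedding)
  emb_d <- lapply(detections, function(d) d$embedding)
  dims <- unique(c(vapply(emb_t[!vapply(emb_t, is.null, TRUE)], length, 1L),
                   vapply(emb_d[!vapply(emb_d, is.null, TRUE)], length, 1L)))
  if (length(dims) > 1L)
    stop("appearance embeddings have inconsistent dimensions", call. = FALSE)

  w <- cfg$w_app_min + (cfg$w_app_max - cfg$w_app_min) *
    trust_of(vapply(detections, function(d) d$conf, 1), cfg)
  app <- matrix(0, n, m)
  have <- outer(!vapply(emb_t, is.null, TRUE), !vapply(emb_d, is.null, TRUE),
                "&")
  if (any(have)) {
    ET <- do.call(rbind, lapply(emb_t, function(e) if (is.null(e))
      numeric(dims[1]) else e))
    ED <- do.call(rbind, lapply(emb_d, function(e) if (is.null(e))
      numeric(dims[1]) else e))
    app <- (1 - tcrossprod(ET, ED)) / 2
  }
  W <- matrix(w, n, m, byrow = TRUE)
  W[!have] <- 0
  cost <- (1 - W) * motion + W * app
  cost[cost > cfg$gate] <- Inf
  # gating cascade: appearance may refine but never override motion
  mg <- cfg$motion_gate %||% 0.95
  cost[motion > mg] <- Inf
  cost
}

#' One-to-one association of tracks to detections
#'
#' Minimum-cost assignment via the Hungarian algorithm; pairs whose cost
#' exceeds the gate (marked `Inf` in the matrix) are dissolved into the
#' unmatched sets.
#'
#' @param cost Cost matrix (tracks x detections), `Inf` = forbidden.
#' @param gate Additional scalar gate applied to the matched costs.
#' @return A list with `matches` (2-column matrix of track/detection
#'   indices), `unmatched_tracks` and `unmatched_detections`.
#' @export
associate <- function(cost, gate = Inf) {
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L || m == 0L)
    return(list(matches = matrix(0L, 0L, 2L),
                unmatched_tracks = seq_len(n),
                unmatched_detections = seq_len(m)))
  sol <- solve_assignment(cost)
  keep <- cost[cbind(sol$rows, sol$cols)] <= gate
  matches <- cbind(track = sol$rows[keep], detection = sol$cols[keep])
  list(matches = matches,
       unmatched_tracks = setdiff(seq_len(n), matches[, 1]),
       unmatched_detections = setdiff(seq_len(m), matches[, 2]))
}

#' Create an empty tracker state
#'
#' @param cfg A [tracker_config()].
#' @return A list of class `"tracker_state"`.
#' @export
tracker_state <- function(cfg = tracker_config()) {
  structure(list(cfg = cfg, tracks = list(), next_id = 1L,
                 last_frame = 0L, records = list()),
            class = "tracker_state")
}

track_class <- function(t) which.max(t$class_votes) - 1L

#' Advance the tracker by one frame
#'
#' The tracking-by-detection loop: predict every live track one frame ahead
#' (optionally warping predictions by camera-motion compensation); associate
#' confirmed tracks to detections with the blended motion/appearance cost,
#' then the remaining (tentative) tracks by motion-only cost; re-anchor lost
#' tracks observation-centrically on re-association (state reset to the last
#' observed box, velocity recomputed from the observation pair, then the
#' regular update); spawn tentative tracks from unmatched detections; kill
#' tracks that have coasted past `max_age`. Confirmed tracks' updates are
#' recorded; a track reaching `min_hits` emits its buffered tentative-phase
#' observations retroactively.
#'
#' @param state A `"tracker_state"`.
#' @param detections List of [detection()] objects for this frame.
#' @param frame 1-based frame index; must exceed the previous frame.
#' @return The updated state; `state$frame_assignments` holds this frame's
#'   `(track id, detection index)` pairs.
#' @export
tracker_step <- function(state, detections, frame) {
  cfg <- state$cfg
  frame <- as.integer(frame)
  if (frame <= state$last_frame)
    stop(sprintf("frames must be presented in increasing order (got %d after %d)",
                 frame, state$last_frame), call. = FALSE)
  state$last_frame <- frame

  # predict
  state$tracks <- lapply(state$tracks, kalman_predict)
  pred_boxes <- if (length(state$tracks))
    do.call(rbind, lapply(state$tracks, track_predicted_box))
    else matrix(numeric(0), 0L, 4L)
  if (!is.null(cfg$cmc) && nrow(pred_boxes)) {
    pred_boxes <- cfg$cmc(frame, pred_boxes)
    # the compensation warps the track states themselves (velocities are
    # left alone: a per-frame camera shift is not object motion)
    for (i in seq_along(state$tracks)) {
      state$tracks[[i]]$mean[1:4] <- box_to_z(pred_boxes[i, ])
      state$tracks[[i]]$last_obs <- cfg$cmc(frame,
        matrix(state$tracks[[i]]$last_obs, 1L))[1, ]
    }
  }

  conf_idx <- which(vapply(state$tracks, function(t)
    t$status == "confirmed", TRUE))
  tent_idx <- setdiff(seq_along(state$tracks), conf_idx)

  det_idx <- seq_along(detections)
  assigned <- matrix(0L, 0L, 2L)                 # (track index, det index)

  # stage 1: confirmed tracks, blended cost
  if (length(conf_idx) && length(det_idx)) {
    cost <- association_cost(state$tracks[conf_idx], detections, cfg,
                             pred_boxes[conf_idx, , drop = FALSE])
    a <- associate(cost, cfg$gate)
    if (nrow(a$matches))
      assigned <- rbind(assigned, cbind(conf_idx[a$matches[, 1]],
                                        a$matches[, 2]))
    det_rem <- det_idx[a$unmatched_detections]
    trk_rem <- c(conf_idx[a$unmatched_tracks], tent_idx)
  } else {
    det_rem <- det_idx
    trk_rem <- c(conf_idx, tent_idx)
  }

  # stage 2: remaining tracks, motion-only cost. Tentative tracks have no
  # velocity estimate yet, so a fast 5-px target may not overlap its own
  # one-frame-old box at all; the NWD motion cost stays informative for
  # non-overlapping tiny boxes and is used here regardless of the metric
  # configured for the confirmed stage.
  if (length(trk_rem) && length(det_rem)) {
    cfg2 <- cfg; cfg2$w_app_min <- 0; cfg2$w_app_max <- 0
    cfg2$motion_metric <- "nwd"
    cfg2$gate <- cfg$bootstrap_gate %||% 0.5
    cfg2$motion_gate <- cfg2$gate
    cost <- association_cost(state$tracks[trk_rem],
                             detections[det_rem], cfg2,
                             pred_boxes[trk_rem, , drop = FALSE])
    a <- associate(cost, cfg2$gate)
    if (nrow(a$matches))
      assigned <- rbind(assigned, cbind(trk_rem[a$matches[, 1]],
                                        det_rem[a$matches[, 2]]))
    det_rem <- det_rem[a$unmatched_detections]
  }

  # updates
  frame_assignments <- matrix(0L, 0L, 2L)
  if (nrow(assigned)) {
    for (r in seq_len(nrow(assigned))) {
      ti <- assigned[r, 1]; di <- assigned[r, 2]
      t <- state$tracks[[ti]]
      d <- detections[[di]]
      if (t$time_since_update > 1L) {
        # observation-centric recovery: re-anchor on the last observed box,
        # velocity from the observation pair across the occlusion gap
        gap <- frame - t$last_obs_frame
        z_old <- box_to_z(t$last_obs)
        z_new <- box_to_z(d$box)
        t$mean <- c(z_old, (z_new[1:2] - z_old[1:2]) / gap, 0, 0)
        size <- (z_old[3] + z_old[4]) / 2
        t$cov <- diag(c(rep((size / 4)^2, 4), rep((size / 8)^2, 2),
                        rep(0, 2)))
      }
      t$embedding <- appearance_update(t, d, cfg)
      t <- kalman_update(t, d, frame)
      rec <- list(frame = frame, box = track_posterior_box(t),
                  conf = d$conf, class_id = d$class_id)
      if (t$status == "confirmed") {
        state$records[[length(state$records) + 1L]] <-
          c(list(id = t$id), rec)
      } else {
        t$pending[[length(t$pending) + 1L]] <- rec
        if (t$hits >= cfg$min_hits) {
          t$status <- "confirmed"
          for (p in t$pending)
            state$records[[length(state$records) + 1L]] <-
              c(list(id = t$id), p)
          t$pending <- list()
        }
      }
      state$tracks[[ti]] <- t
      frame_assignments <- rbind(frame_assignments, c(t$id, di))
    }
  }

  # births
  for (di in det_rem) {
    t <- kalman_init(detections[[di]], id = state$next_id, frame = frame)
    if (cfg$min_hits <= 1L) {
      t$status <- "confirmed"
      for (p in t$pending)
        state$records[[length(state$records) + 1L]] <- c(list(id = t$id), p)
      t$pending <- list()
    }
    state$next_id <- state$next_id + 1L
    state$tracks[[length(state$tracks) + 1L]] <- t
    frame_assignments <- rbind(frame_assignments, c(t$id, di))
  }

  # deaths: confirmed tracks may coast up to max_age; a tentative track
  # missing its very next frame is discarded (it has earned no trust yet)
  keep <- vapply(state$tracks, function(t) {
    if (t$status == "confirmed") t$time_since_update <= cfg$max_age
    else t$time_since_update == 0L
  }, TRUE)
  state$tracks <- state$tracks[keep]

  state$frame_assignments <- frame_assignments
  state
}

#' Run the tracker over a detection stream
#'
#' @param stream Either a list of per-frame lists of [detection()] objects
#'   (frame `i` at position `i`), or a `"detection_set"` as produced by
#'   [degrade_to_detections()] / [read_detections()].
#' @param cfg A [tracker_config()].
#' @return A trajectory set: `data.frame(frame, id, x1, y1, x2, y2, conf,
#'   class_id)` sorted by frame then id. Deterministic given inputs and
#'   configuration; ids are dense positive integers in order of creation.
#' @export
tracker_run <- function(stream, cfg = tracker_config()) {
  frames <- as_detection_frames(stream)
  state <- tracker_state(cfg)
  for (f in seq_along(frames))
    state <- tracker_step(state, frames[[f]], f)
  records_to_trajectories(state$records)
}

records_to_trajectories <- function(records) {
  if (!length(records))
    return(data.frame(frame = integer(0), id = integer(0),
                      x1 = numeric(0), y1 = numeric(0),
                      x2 = numeric(0), y2 = numeric(0),
                      conf = numeric(0), class_id = integer(0)))
  df <- data.frame(
    frame = vapply(records, function(r) r$frame, 1L),
    id = vapply(records, function(r) r$id, 1L),
    x1 = vapply(records, function(r) r$box[1], 1),
    y1 = vapply(records, function(r) r$box[2], 1),
    x2 = vapply(records, function(r) r$box[3], 1),
    y2 = vapply(records, function(r) r$box[4], 1),
    conf = vapply(records, function(r) r$conf, 1),
    class_id = vapply(records, function(r) r$class_id, 1L)
  )
  df[order(df$frame, df$id), , drop = FALSE]
}

# Normalise tracker input into a list of per-frame detection lists.
as_detection_frames <- function(stream) {
  if (inherits(stream, "detection_set")) {
    df <- stream$detections
    emb <- stream$embeddings
    nframes <- stream$n_frames %||% if (nrow(df)) max(df$frame) else 0L
    frames <- vector("list", nframes)
    for (f in seq_len(nframes)) frames[[f]] <- list()
    if (nrow(df)) {
      for (i in seq_len(nrow(df))) {
        f <- df$frame[i]
        frames[[f]][[length(frames[[f]]) + 1L]] <- detection(
          c(df$x1[i], df$y1[i], df$x2[i], df$y2[i]),
          class_id = df$class_id[i], conf = df$conf[i],
          embedding = if (!is.null(emb)) emb[i, ] else NULL)
      }
    }
    return(frames)
  }
  if (is.list(stream)) return(stream)
  stop("unsupported detection stream", call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
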