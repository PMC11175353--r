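#' @name kalman
#' @title Constant-velocity Kalman filter over box state
#'
#' @description
#' Each track carries an 8-dimensional state `(cx, cy, w, h, vcx, vcy, vw,
#' vh)` — box centre, size, and their per-frame velocities. The centre
#' follows a constant-velocity model; the size is quasi-static (sperm heads
#' are rigid, so the size-velocity components are kept at zero and the size
#' evolves as a slow random walk, making the estimate an exponentially
#' weighted average of the observed sizes). Noise scales are tied to box
#' size so the same configuration serves 5-pixel sperm heads and larger
#' clusters: per frame, the centre process noise adapts to the track's own
#' speed estimate (lateral acceleration of a persistent random walk scales
#' with speed; standard deviation `0.15 * speed`, floored at `size/40`),
#' the size process noise is `size/200`, and the centre-velocity noise is
#' `0.08 * speed` floored at `size/200`. Measurement noise is
#' confidence-adaptive: at zero confidence
#' the standard deviation is a third of the box size on the centre and
#' twice that on the size (a detector's width estimate for a tiny object is
#' far noisier than its localisation), and both scale by
#' `(1 - confidence)`, so a confidence-1 detection is adopted exactly.
NULL

.track_id_counter <- new.env(parent = emptyenv())
.track_id_counter$id <- 0L

next_track_id <- function() {
  .track_id_counter$id <- .track_id_counter$id + 1L
  .track_id_counter$id
}

reset_track_ids <- function() .track_id_counter$id <- 0L

box_to_z <- function(b) {
  c((b[[1]] + b[[3]]) / 2, (b[[2]] + b[[4]]) / 2,
    b[[3]] - b[[1]], b[[4]] - b[[2]])
}

z_to_box <- function(z) {
  c(z[1] - z[3] / 2, z[2] - z[4] / 2, z[1] + z[3] / 2, z[2] + z[4] / 2)
}

kf_F <- local({
  F <- diag(8)
  F[1:2, 5:6] <- diag(2)   # centre integrates its velocity; size does not
  F
})
kf_H <- cbind(diag(4), matrix(0, 4, 4))

kf_Q <- function(size, speed = 0) {
  # lateral acceleration of a persistent random walk scales with speed
  # (delta-heading times speed per frame), so the centre process noise
  # adapts to the track's own velocity estimate, with a size-scaled floor
  # for slow or newborn tracks
  qa <- max(0.15 * speed, size / 40)
  qb <- max(0.08 * speed, size / 200)
  diag(c(rep(qa^2, 2), rep((size / 200)^2, 2), rep(qb^2, 2), rep(0, 2)))
}

kf_R <- function(size, conf) {
  f <- 1 - min(max(conf, 0), 1)
  # centre: confidence-adaptive (NSA); a confidence-1 detection is adopted
  # exactly. size: fixed noise floor — the quasi-static size state averages
  # measurements instead of chasing single-frame size jitter, and since a
  # noise-free stream observes the true constant size from the first frame,
  # the size estimate is still exact in that regime.
  diag(c(rep((size / 3 * f)^2, 2), rep((size / 4)^2, 2)))
}

#' A single per-frame detection
#'
#' @param box The detected box ([bbox()] or numeric `c(x1, y1, x2, y2)`).
#' @param class_id Integer class (0 = sperm, 1 = cluster, 2 = small/pinhead).
#' @param conf Detection confidence in `[0, 1]`.
#' @param embedding Optional appearance embedding; normalised to unit length.
#' @return A list of class `"detection"`.
#' @export
detection <- function(box, class_id = 0L, conf = 1, embedding = NULL) {
  validate_box(box, "box")
  if (conf < 0 || conf > 1) stop("conf must lie in [0, 1]", call. = FALSE)
  if (!is.null(embedding)) {
    nrm <- sqrt(sum(embedding^2))
    if (nrm == 0) stop("embedding must be nonzero", call. = FALSE)
    embedding <- embedding / nrm
  }
  structure(list(box = as.numeric(box), class_id = as.integer(class_id),
                 conf = as.numeric(conf), embedding = embedding),
            class = "detection")
}

#' Initialise a track from a detection
#'
#' The state mean is the detection's `(cx, cy, w, h)` with zero velocities;
#' the initial covariance scales with box size (standard deviation `size/4`
#' on observed components, `size/2` per frame on velocities — wide, since a
#' single observation says nothing about motion). Tracks start `tentative`
#' and carry a fresh, never-reused id.
#'
#' @param d A [detection()].
#' @param id Track id; defaults to a package-level counter.
#' @param frame Frame index of the detection (1-based).
#' @return A list of class `"track_state"`.
#' @export
kalman_init <- function(d, id = next_track_id(), frame = 1L) {
  z <- box_to_z(d$box)
  size <- (z[3] + z[4]) / 2
  P <- diag(c(rep((size / 4)^2, 4), rep((size / 2)^2, 2), rep(0, 2)))
  structure(list(
    id = as.integer(id),
    mean = c(z, 0, 0, 0, 0),
    cov = P,
    embedding = d$embedding,
    hits = 1L, age = 1L, time_since_update = 0L,
    status = "tentative",
    last_obs = d$box, last_obs_frame = as.integer(frame),
    conf = d$conf,
    class_votes = tabulate_class(d$class_id),
    pending = list(list(frame = as.integer(frame), box = d$box,
                        conf = d$conf, class_id = d$class_id))
  ), class = "track_state")
}

tabulate_class <- function(class_id, votes = integer(3)) {
  i <- class_id + 1L
  if (i >= 1L && i <= length(votes)) votes[i] <- votes[i] + 1L
  votes
}

#' Predict a track one frame ahead
#'
#' Constant-velocity advance of the mean; the covariance grows by
#' size-scaled process noise. Age and `time_since_update` are incremented.
#'
#' @param t A `"track_state"`.
#' @return The advanced track state.
#' @export
kalman_predict <- function(t) {
  t$mean <- as.numeric(kf_F %*% t$mean)
  # a shrinking-size prediction is clamped: boxes cannot have nonpositive size
  t$mean[3] <- max(t$mean[3], 1e-3)
  t$mean[4] <- max(t$mean[4], 1e-3)
  size <- (t$mean[3] + t$mean[4]) / 2
  t$cov <- kf_F %*% t$cov %*% t(kf_F) +
    kf_Q(size, sqrt(sum(t$mean[5:6]^2)))
  t$age <- t$age + 1L
  t$time_since_update <- t$time_since_update + 1L
  t
}

#' Correct a track with a matched detection
#'
#' Standard gain-weighted Kalman correction with confidence-scaled
#' measurement noise: the posterior mean moves toward the observed
#' `(cx, cy, w, h)` by the Kalman gain, and for a confidence-1 detection the
#' measurement noise vanishes, so the posterior equals the observation in
#' the measured subspace. `time_since_update` resets; `hits` increments.
#'
#' @param t A `"track_state"` (after [kalman_predict()]).
#' @param d The matched [detection()].
#' @param frame Frame index of the update.
#' @return The corrected track state.
#' @export
kalman_update <- function(t, d, frame = t$last_obs_frame + t$time_since_update) {
  z <- box_to_z(d$box)
  size <- (z[3] + z[4]) / 2
  R <- kf_R(size, d$conf)
  S <- kf_H %*% t$cov %*% t(kf_H) + R
  K <- t$cov %*% t(kf_H) %*% solve(S)
  innov <- z - as.numeric(kf_H %*% t$mean)
  t$mean <- as.numeric(t$mean + K %*% innov)
  IKH <- diag(8) - K %*% kf_H
  # Joseph form keeps the covariance symmetric positive definite even when
  # the adaptive measurement noise collapses to zero
  t$cov <- IKH %*% t$cov %*% t(IKH) + K %*% R %*% t(K)
  t$cov <- (t$cov + t(t$cov)) / 2
  t$hits <- t$hits + 1L
  t$time_since_update <- 0L
  t$last_obs <- d$box
  t$last_obs_frame <- as.integer(frame)
  t$conf <- d$conf
  t$class_votes <- tabulate_class(d$class_id, t$class_votes)
  t
}

track_predicted_box <- function(t) z_to_box(t$mean[1:4])

track_posterior_box <- function(t) z_to_box(t$mean[1:4])
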