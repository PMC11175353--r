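#' Simulator configuration
#'
#' Defaults emulate the statistics of wet-preparation semen microscopy
#' video: 640 x 480 px frames, about 200 motile sperm in view, head sizes 5
#' to 7 px, 30-second clips (750 frames at 25 fps), and the three annotated
#' classes (sperm, cluster, small/pinhead). Motion is a persistent random
#' walk — near-constant speed with Gaussian heading diffusion — which mimics
#' progressive motility confined to the focal plane.
#'
#' @param width,height Frame size in pixels.
#' @param n_frames Number of frames (default 750, i.e. 30 s at 25 fps).
#' @param n Number of tracked objects (default 200).
#' @param head_size Range (min, max) of per-identity head size in pixels.
#' @param class_mix Proportions of the classes `sperm`, `cluster`,
#'   `pinhead`; must sum to 1.
#' @param speed_mean,speed_sd Per-identity mean speed distribution
#'   (truncated normal, px/frame).
#' @param heading_sigma Standard deviation of the per-frame Gaussian heading
#'   increment (radians); 0 gives straight-line motion.
#' @param embed_dim Dimension of the per-identity latent appearance vectors.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(width = 640L, height = 480L, n_frames = 750L,
                       n = 200L, head_size = c(5, 7),
                       class_mix = c(sperm = 0.85, cluster = 0.05,
                                     pinhead = 0.10),
                       speed_mean = 2, speed_sd = 0.8,
                       heading_sigma = 0.15, embed_dim = 16L) {
  if (n < 0) stop("n must be nonnegative", call. = FALSE)
  if (any(head_size <= 0)) stop("head sizes must be positive", call. = FALSE)
  if (abs(sum(class_mix) - 1) > 1e-9 || any(class_mix < 0))
    stop("class_mix proportions must be nonnegative and sum to 1",
         call. = FALSE)
  if (embed_dim < 2L) stop("embed_dim must be at least 2", call. = FALSE)
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_frames = as.integer(n_frames), n = as.integer(n),
                 head_size = head_size, class_mix = class_mix,
                 speed_mean = speed_mean, speed_sd = speed_sd,
                 heading_sigma = heading_sigma,
                 embed_dim = as.integer(embed_dim)),
            class = "sim_config")
}

#' Detector-imperfection (noise) configuration
#'
#' Defaults are the degraded study conditions: 5% missed detections, 1 px
#' corner jitter, a budget of 10 false positives per frame, and confidences
#' drawn around 0.85 for true detections and 0.3 for false positives.
#'
#' @param miss_prob Probability a ground-truth box is dropped.
#' @param fp_rate Poisson mean of false positives per frame.
#' @param jitter_sd Gaussian standard deviation added i.i.d. to each box
#'   corner coordinate (px).
#' @param conf_mean,conf_sd Confidence model of true detections (Gaussian,
#'   clipped to `[0, 1]`).
#' @param fp_conf_mean,fp_conf_sd Confidence model of false positives.
#' @param embed_noise Standard deviation of the Gaussian perturbation added
#'   to the identity's latent appearance vector before renormalisation.
#' @return A list of class `"noise_config"`.
#' @export
noise_config <- function(miss_prob = 0.05, fp_rate = 10, jitter_sd = 1,
                         conf_mean = 0.85, conf_sd = 0.1,
                         fp_conf_mean = 0.3, fp_conf_sd = 0.1,
                         embed_noise = 0.1) {
  stopifnot(miss_prob >= 0, miss_prob <= 1, fp_rate >= 0, jitter_sd >= 0,
            embed_noise >= 0)
  structure(list(miss_prob = miss_prob, fp_rate = fp_rate,
                 jitter_sd = jitter_sd, conf_mean = conf_mean,
                 conf_sd = conf_sd, fp_conf_mean = fp_conf_mean,
                 fp_conf_sd = fp_conf_sd, embed_noise = embed_noise),
            class = "noise_config")
}

#' Zero-noise configuration (detections reproduce the ground truth exactly)
#'
#' @return A [noise_config()] with every noise source off and confidence 1.
#' @export
noise_config_clean <- function() {
  noise_config(miss_prob = 0, fp_rate = 0, jitter_sd = 0,
               conf_mean = 1, conf_sd = 0, embed_noise = 0)
}

class_names <- c("sperm", "cluster", "pinhead")

#' Simulate ground-truth trajectories
#'
#' Each identity follows a persistent random walk: a per-identity speed is
#' drawn once, the heading diffuses by Gaussian increments each frame, and
#' the box centre reflects off the frame boundary so every box stays fully
#' inside the frame at all times. The head size is drawn once per identity
#' from the configured range; clusters (several heads sharing one box) get
#' a box about twice the head size and pinheads 60% of the minimum size.
#' Deterministic given the RNG state (set a seed before calling).
#'
#' @param cfg A [sim_config()].
#' @return A list of class `"ground_truth_set"`: `traj` (trajectory
#'   `data.frame(frame, id, x1, y1, x2, y2, conf, class_id)`), `classes`
#'   (per-identity class), `latents` (`n x embed_dim` unit-norm appearance
#'   matrix), `cfg`.
#' @export
simulate_trajectories <- function(cfg = sim_config()) {
  n <- cfg$n
  traj <- vector("list", n)
  classes <- integer(n)
  latents <- matrix(0, n, cfg$embed_dim)
  if (n > 0L) {
    cls_levels <- seq_along(cfg$class_mix) - 1L
    classes <- sample(cls_levels, n, replace = TRUE, prob = cfg$class_mix)
    for (i in seq_len(n)) {
      size <- stats::runif(1, cfg$head_size[1], cfg$head_size[2])
      if (classes[i] == 1L) size <- size * stats::runif(1, 1.8, 2.5)
      if (classes[i] == 2L) size <- 0.6 * cfg$head_size[1]
      half <- size / 2
      speed <- max(0.2, stats::rnorm(1, cfg$speed_mean, cfg$speed_sd))
      if (classes[i] == 1L) speed <- speed * 0.3   # clusters barely drift
      heading <- stats::runif(1, 0, 2 * pi)
      cx <- stats::runif(1, half, cfg$width - half)
      cy <- stats::runif(1, half, cfg$height - half)
      xs <- numeric(cfg$n_frames); ys <- numeric(cfg$n_frames)
      for (f in seq_len(cfg$n_frames)) {
        xs[f] <- cx; ys[f] <- cy
        heading <- heading + stats::rnorm(1, 0, cfg$heading_sigma)
        cx <- cx + speed * cos(heading)
        cy <- cy + speed * sin(heading)
        # reflective boundaries keep the whole box inside the frame
        if (cx < half) { cx <- 2 * half - cx; heading <- pi - heading }
        if (cx > cfg$width - half) {
          cx <- 2 * (cfg$width - half) - cx; heading <- pi - heading
        }
        if (cy < half) { cy <- 2 * half - cy; heading <- -heading }
        if (cy > cfg$height - half) {
          cy <- 2 * (cfg$height - half) - cy; heading <- -heading
        }
      }
      traj[[i]] <- data.frame(frame = seq_len(cfg$n_frames), id = i,
                              x1 = xs - half, y1 = ys - half,
                              x2 = xs + half, y2 = ys + half,
                              conf = 1, class_id = classes[i])
      e <- stats::rnorm(cfg$embed_dim)
      latents[i, ] <- e / sqrt(sum(e^2))
    }
  }
  df <- if (n > 0L) do.call(rbind, traj)
        else data.frame(frame = integer(0), id = integer(0), x1 = numeric(0),
                        y1 = numeric(0), x2 = numeric(0), y2 = numeric(0),
                        conf = numeric(0), class_id = integer(0))
  df <- df[order(df$frame, df$id), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(traj = df, classes = classes, latents = latents, cfg = cfg),
            class = "ground_truth_set")
}

#' Degrade ground truth into imperfect detections
#'
#' Each ground-truth box is independently dropped with the miss
#' probability; survivors get i.i.d. Gaussian jitter on all four corners, a
#' sampled confidence, and a noisy appearance embedding drawn around the
#' identity's latent vector. Poisson-many false positives per frame receive
#' random in-frame boxes, low confidences and random embeddings.
#' Deterministic given the RNG state.
#'
#' @param gt A `"ground_truth_set"` from [simulate_trajectories()].
#' @param noise A [noise_config()].
#' @return A list of class `"detection_set"`: `detections`
#'   (`data.frame(frame, x1, y1, x2, y2, conf, class_id, gt_id)`, `gt_id`
#'   `NA` for false positives), `embeddings` (row-aligned matrix), and
#'   `n_frames`.
#' @export
degrade_to_detections <- function(gt, noise = noise_config()) {
  cfg <- gt$cfg
  df <- gt$traj
  D <- cfg$embed_dim
  keep <- if (noise$miss_prob > 0)
    stats::runif(nrow(df)) >= noise$miss_prob else rep(TRUE, nrow(df))
  kept <- df[keep, , drop = FALSE]
  m <- nrow(kept)
  if (m > 0L) {
    if (noise$jitter_sd > 0) {
      jit <- matrix(stats::rnorm(4L * m, 0, noise$jitter_sd), m, 4L)
      kept$x1 <- kept$x1 + jit[, 1]; kept$y1 <- kept$y1 + jit[, 2]
      kept$x2 <- kept$x2 + jit[, 3]; kept$y2 <- kept$y2 + jit[, 4]
      # jitter must not produce degenerate boxes
      bad <- kept$x2 - kept$x1 < 0.5
      kept$x2[bad] <- kept$x1[bad] + 0.5
      bad <- kept$y2 - kept$y1 < 0.5
      kept$y2[bad] <- kept$y1[bad] + 0.5
    }
    conf <- if (noise$conf_sd > 0)
      pmin(pmax(stats::rnorm(m, noise$conf_mean, noise$conf_sd), 0), 1)
      else rep(noise$conf_mean, m)
    emb <- gt$latents[kept$id, , drop = FALSE]
    if (noise$embed_noise > 0)
      emb <- emb + matrix(stats::rnorm(m * D, 0, noise$embed_noise), m, D)
    emb <- emb / sqrt(rowSums(emb^2))
    dets <- data.frame(frame = kept$frame, x1 = kept$x1, y1 = kept$y1,
                       x2 = kept$x2, y2 = kept$y2, conf = conf,
                       class_id = kept$class_id, gt_id = kept$id)
  } else {
    dets <- data.frame(frame = integer(0), x1 = numeric(0), y1 = numeric(0),
                       x2 = numeric(0), y2 = numeric(0), conf = numeric(0),
                       class_id = integer(0), gt_id = integer(0))
    emb <- matrix(0, 0L, D)
  }
  if (noise$fp_rate > 0) {
    nfp <- stats::rpois(cfg$n_frames, noise$fp_rate)
    total <- sum(nfp)
    if (total > 0L) {
      sz <- stats::runif(total, cfg$head_size[1], cfg$head_size[2])
      x1 <- stats::runif(total, 0, cfg$width - sz)
      y1 <- stats::runif(total, 0, cfg$height - sz)
      fpc <- pmin(pmax(stats::rnorm(total, noise$fp_conf_mean,
                                    noise$fp_conf_sd), 0), 1)
      fpe <- matrix(stats::rnorm(total * D), total, D)
      fpe <- fpe / sqrt(rowSums(fpe^2))
      fpd <- data.frame(frame = rep(seq_len(cfg$n_frames), nfp),
                        x1 = x1, y1 = y1, x2 = x1 + sz, y2 = y1 + sz,
                        conf = fpc, class_id = 0L, gt_id = NA_integer_)
      dets <- rbind(dets, fpd)
      emb <- rbind(emb, fpe)
    }
  }
  ord <- order(dets$frame)
  dets <- dets[ord, , drop = FALSE]
  emb <- emb[ord, , drop = FALSE]
  rownames(dets) <- NULL
  structure(list(detections = dets, embeddings = emb,
                 n_frames = cfg$n_frames),
            class = "detection_set")
}

#' Render simulated frames as grayscale images
#'
#' Dark elliptical heads at the box centres (pinheads darker), a thin curved
#' tail trailing each head opposite its heading, light background with
#' Gaussian sensor noise. Intended for demos and visual checks, not for
#' photorealism.
#'
#' @param gt A `"ground_truth_set"`.
#' @param frames Which frames to render (default all).
#' @param bg Background intensity in `[0, 1]`.
#' @param noise_sd Sensor noise standard deviation.
#' @return A list of `height x width` matrices with values in `[0, 1]`.
#' @export
render_frames <- function(gt, frames = NULL, bg = 0.85, noise_sd = 0.02) {
  cfg <- gt$cfg
  if (is.null(frames)) frames <- seq_len(cfg$n_frames)
  df <- gt$traj
  out <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    f <- frames[k]
    img <- matrix(bg, cfg$height, cfg$width)
    if (noise_sd > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, noise_sd),
                          cfg$height, cfg$width)
    rows <- df[df$frame == f, , drop = FALSE]
    if (nrow(rows)) {
      prev <- df[df$frame == max(1L, f - 1L), , drop = FALSE]
      for (r in seq_len(nrow(rows))) {
        cx <- (rows$x1[r] + rows$x2[r]) / 2
        cy <- (rows$y1[r] + rows$y2[r]) / 2
        a <- (rows$x2[r] - rows$x1[r]) / 2
        b <- (rows$y2[r] - rows$y1[r]) / 2
        shade <- if (rows$class_id[r] == 2L) 0.05 else 0.2
        xr <- max(1L, floor(cx - a)):min(cfg$width, ceiling(cx + a))
        yr <- max(1L, floor(cy - b)):min(cfg$height, ceiling(cy + b))
        for (y in yr) for (x in xr) {
          if (((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1) img[y, x] <- shade
        }
        # tail: trail opposite the last displacement, gently curved
        pr <- prev[prev$id == rows$id[r], , drop = FALSE]
        if (nrow(pr) == 1L && rows$class_id[r] != 1L) {
          dx <- cx - (pr$x1 + pr$x2) / 2
          dy <- cy - (pr$y1 + pr$y2) / 2
          nrm <- sqrt(dx^2 + dy^2)
          if (nrm > 1e-6) {
            ux <- -dx / nrm; uy <- -dy / nrm
            len <- 4 * (a + b)
            for (s in seq(0, len, by = 0.5)) {
              wob <- 0.6 * sin(s)
              px <- round(cx + ux * s - uy * wob)
              py <- round(cy + uy * s + ux * wob)
              if (px >= 1 && px <= cfg$width && py >= 1 && py <= cfg$height)
                img[py, px] <- min(img[py, px], 0.55)
            }
          }
        }
      }
    }
    out[[k]] <- pmin(pmax(img, 0), 1)
  }
  out
}
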