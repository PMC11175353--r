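#' @name net_ops
#' @title Dense feature-map operators
#'
#' @description
#' The architectural operators of the small-object detector, expressed as
#' plain array transforms. A feature map is a numeric 3-D array with
#' dimensions `(channels, height, width)`. All operators are deterministic
#' given their parameters and preserve finiteness; each states its exact
#' output shape.
NULL

as_feature_map <- function(f) {
  if (is.matrix(f)) f <- array(f, c(1L, nrow(f), ncol(f)))
  if (!is.array(f) || length(dim(f)) != 3L || !is.numeric(f))
    stop("feature map must be a numeric (channels, height, width) array",
         call. = FALSE)
  f
}

#' Space-to-depth rearrangement
#'
#' Folds each `scale x scale` spatial block into the channel axis: the output
#' has shape `(C * scale^2, H / scale, W / scale)`. The rearrangement is a
#' bijection — every input element appears exactly once in the output — with
#' sub-pixel offsets ordered row-major: output channel block `(dy, dx)` (dy
#' the row offset varying slowest) holds the input pixels at
#' `(y * scale + dy, x * scale + dx)`. [depth_to_space()] is its exact
#' inverse, so downsampling by this operator discards nothing.
#'
#' @param f Feature map `(C, H, W)`; `H` and `W` must be divisible by `scale`.
#' @param scale Integer block size; `scale = 1` is the identity.
#' @return Feature map `(C * scale^2, H / scale, W / scale)`.
#' @export
space_to_depth <- function(f, scale) {
  f <- as_feature_map(f)
  scale <- as.integer(scale)
  if (scale < 1L) stop("scale must be a positive integer", call. = FALSE)
  d <- dim(f)
  if (d[2] %% scale != 0L || d[3] %% scale != 0L)
    stop(sprintf("H (%d) and W (%d) must be divisible by scale (%d)",
                 d[2], d[3], scale), call. = FALSE)
  if (scale == 1L) return(f)
  C <- d[1]; Ho <- d[2] %/% scale; Wo <- d[3] %/% scale
  out <- array(0, c(C * scale^2, Ho, Wo))
  blk <- 0L
  for (dy in 0:(scale - 1L)) {
    for (dx in 0:(scale - 1L)) {
      ys <- seq.int(1L + dy, d[2], by = scale)
      xs <- seq.int(1L + dx, d[3], by = scale)
      out[blk * C + seq_len(C), , ] <- f[, ys, xs, drop = FALSE]
      blk <- blk + 1L
    }
  }
  out
}

#' Depth-to-space rearrangement (inverse of [space_to_depth()])
#'
#' @param f Feature map `(C * scale^2, H, W)`.
#' @param scale Integer block size used by the forward rearrangement.
#' @return Feature map `(C, H * scale, W * scale)`.
#' @export
depth_to_space <- function(f, scale) {
  f <- as_feature_map(f)
  scale <- as.integer(scale)
  if (scale < 1L) stop("scale must be a positive integer", call. = FALSE)
  if (scale == 1L) return(f)
  d <- dim(f)
  if (d[1] %% scale^2 != 0L)
    stop("channel count must be divisible by scale^2", call. = FALSE)
  C <- d[1] %/% scale^2
  out <- array(0, c(C, d[2] * scale, d[3] * scale))
  blk <- 0L
  for (dy in 0:(scale - 1L)) {
    for (dx in 0:(scale - 1L)) {
      ys <- seq.int(1L + dy, d[2] * scale, by = scale)
      xs <- seq.int(1L + dx, d[3] * scale, by = scale)
      out[, ys, xs] <- f[blk * C + seq_len(C), , , drop = FALSE]
      blk <- blk + 1L
    }
  }
  out
}

# 2-D convolution, stride 1, zero "same" padding by default.
# weight: (C_out, C_in, kh, kw); bias: length C_out or NULL.
conv2d <- function(f, weight, bias = NULL, pad = "same") {
  f <- as_feature_map(f)
  d <- dim(f); wd <- dim(weight)
  if (length(wd) != 4L || wd[2] != d[1])
    stop(sprintf("weight (C_out, C_in, kh, kw) must have C_in = %d", d[1]),
         call. = FALSE)
  kh <- wd[3]; kw <- wd[4]
  if (identical(pad, "same")) pad <- c((kh - 1L) %/% 2L, (kw - 1L) %/% 2L)
  ph <- pad[1]; pw <- pad[length(pad)]
  Hp <- d[2] + 2L * ph; Wp <- d[3] + 2L * pw
  fp <- array(0, c(d[1], Hp, Wp))
  fp[, ph + seq_len(d[2]), pw + seq_len(d[3])] <- f
  Ho <- Hp - kh + 1L; Wo <- Wp - kw + 1L
  out <- array(0, c(wd[1], Ho, Wo))
  for (o in seq_len(wd[1])) {
    acc <- matrix(0, Ho, Wo)
    for (i in seq_len(d[1])) {
      for (ki in seq_len(kh)) {
        for (kj in seq_len(kw)) {
          w <- weight[o, i, ki, kj]
          if (w != 0)
            acc <- acc + w * fp[i, ki - 1L + seq_len(Ho), kj - 1L + seq_len(Wo)]
        }
      }
    }
    out[o, , ] <- acc + if (is.null(bias)) 0 else bias[o]
  }
  out
}

# Depth-wise 2-D convolution: weight (C, kh, kw), one kernel per channel.
depthwise_conv2d <- function(f, weight, bias = NULL, pad = "same") {
  f <- as_feature_map(f)
  d <- dim(f); wd <- dim(weight)
  if (length(wd) != 3L || wd[1] != d[1])
    stop("depthwise weight must be (C, kh, kw) matching the input channels",
         call. = FALSE)
  out <- array(0, c(d[1], d[2], d[3]))
  for (ch in seq_len(d[1])) {
    w4 <- array(weight[ch, , ], c(1L, 1L, wd[2], wd[3]))
    out[ch, , ] <- conv2d(f[ch, , , drop = FALSE], w4,
                          bias = if (is.null(bias)) NULL else bias[ch],
                          pad = pad)
  }
  out
}

#' Space-to-depth convolution (SPDConv)
#'
#' [space_to_depth()] followed by a stride-1 convolution: spatial resolution
#' drops by `scale` while every input element survives into the channel axis,
#' so — unlike a strided convolution — no fine-grained information is
#' discarded before the learned mixing. This is the downsampling block that
#' replaces stride-2 3x3 convolutions in the small-object detector.
#'
#' @param f Feature map `(C, H, W)` with `H`, `W` divisible by `scale`.
#' @param params List with `scale`, `weight` `(C_out, C * scale^2, kh, kw)`
#'   and optional `bias` (length `C_out`). See [spd_conv_params()].
#' @return Feature map `(C_out, H / scale, W / scale)`.
#' @export
spd_conv <- function(f, params) {
  f <- as_feature_map(f)
  s <- space_to_depth(f, params$scale)
  if (dim(params$weight)[2] != dim(s)[1])
    stop(sprintf("spd_conv weight expects %d input channels, got %d",
                 dim(params$weight)[2], dim(s)[1]), call. = FALSE)
  conv2d(s, params$weight, params$bias)
}

#' Parameters for [spd_conv()]
#'
#' @param c_in,c_out Input/output channel counts.
#' @param scale Downsampling factor (default 2).
#' @param k Kernel size of the non-strided convolution (default 3).
#' @param init `"random"` (standard normal scaled by fan-in) or `"zeros"`.
#' @return Parameter list for [spd_conv()].
#' @export
spd_conv_params <- function(c_in, c_out, scale = 2L, k = 3L,
                            init = "random") {
  cin2 <- c_in * scale^2
  w <- if (init == "zeros") array(0, c(c_out, cin2, k, k))
       else array(stats::rnorm(c_out * cin2 * k * k) / sqrt(cin2 * k * k),
                  c(c_out, cin2, k, k))
  list(scale = as.integer(scale), weight = w, bias = numeric(c_out))
}

#' Parameters of the multi-scale convolutional attention (MSCA) block
#'
#' @param channels Channel count `C` of the feature map.
#' @param kernel_sizes Odd strip-kernel lengths of the three multi-scale
#'   branches (default `c(7, 11, 21)`).
#' @param shortcut Keep the identity shortcut branch (`Scale_0`)?
#' @param base_k Kernel size of the shared leading depth-wise convolution
#'   (default 5).
#' @param init `"random"` or `"zeros"`.
#' @return A list of class `"msca_params"`: `base` `(C, base_k, base_k)`
#'   depth-wise kernel, `branches` (per branch a horizontal `(C, k)` and a
#'   vertical `(C, k)` strip kernel), `mix` `(C, C)` 1x1 mixing kernel with
#'   `mix_bias`, and `shortcut`.
#' @export
msca_params <- function(channels, kernel_sizes = c(7, 11, 21),
                        shortcut = TRUE, base_k = 5L, init = "random") {
  if (any(kernel_sizes %% 2 == 0) || base_k %% 2 == 0)
    stop("MSCA kernel sizes must be odd", call. = FALSE)
  rnd <- function(n, fan) if (init == "zeros") numeric(n)
         else stats::rnorm(n) / sqrt(fan)
  structure(list(
    channels = channels,
    base = array(rnd(channels * base_k^2, base_k^2),
                 c(channels, base_k, base_k)),
    branches = lapply(kernel_sizes, function(k) list(
      k = as.integer(k),
      horiz = matrix(rnd(channels * k, k), channels, k),
      vert = matrix(rnd(channels * k, k), channels, k)
    )),
    mix = matrix(rnd(channels^2, channels), channels, channels),
    mix_bias = numeric(channels),
    shortcut = isTRUE(shortcut)
  ), class = "msca_params")
}

#' Multi-scale convolutional attention (MSCA)
#'
#' `Att = Conv1x1(Scale_0(F) + sum_i Strip_i(DWConv(F)))`, `Out = Att * F`
#' (element-wise). A shared depth-wise convolution aggregates local detail;
#' three decomposed strip-kernel branches (1xk then kx1, k = 7, 11, 21 by
#' default) capture elongated multi-scale context such as sperm tails; the
#' 1x1 convolution mixes channels into an attention map that reweights the
#' input. `Scale_0` is the identity shortcut carrying the module input.
#' Output shape equals input shape.
#'
#' @param f Feature map `(C, H, W)`.
#' @param p An [msca_params()] with matching `C`.
#' @return Feature map `(C, H, W)`.
#' @export
msca_attention <- function(f, p) {
  f <- as_feature_map(f)
  if (dim(f)[1] != p$channels)
    stop(sprintf("MSCA params built for %d channels, input has %d",
                 p$channels, dim(f)[1]), call. = FALSE)
  u <- depthwise_conv2d(f, p$base)
  s <- if (p$shortcut) f else array(0, dim(f))
  for (br in p$branches) {
    h <- depthwise_conv2d(u, array(br$horiz, c(p$channels, 1L, br$k)))
    s <- s + depthwise_conv2d(h, array(br$vert, c(p$channels, br$k, 1L)))
  }
  att <- conv2d(s, array(p$mix, c(p$channels, p$channels, 1L, 1L)),
                p$mix_bias)
  att * f
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' Parameters of the efficient multi-scale attention (EMA) block
#'
#' @param channels Channel count `C`; must be divisible by `groups`.
#' @param groups Number of channel groups `g` (default 4).
#' @param init `"random"` or `"zeros"`.
#' @return A list of class `"ema_params"` with the shared per-group 1x1
#'   kernel (`w1`, `(C/g, C/g)`) and 3x3 kernel (`w3`,
#'   `(C/g, C/g, 3, 3)`) plus biases.
#' @export
ema_params <- function(channels, groups = 4L, init = "random") {
  if (channels %% groups != 0L)
    stop("channels must be divisible by groups", call. = FALSE)
  cg <- channels %/% groups
  rnd <- function(n, fan) if (init == "zeros") numeric(n)
         else stats::rnorm(n) / sqrt(fan)
  structure(list(
    channels = channels, groups = as.integer(groups), cg = cg,
    w1 = matrix(rnd(cg^2, cg), cg, cg), b1 = numeric(cg),
    w3 = array(rnd(9 * cg^2, 9 * cg), c(cg, cg, 3L, 3L)), b3 = numeric(cg)
  ), class = "ema_params")
}

#' Efficient multi-scale attention (EMA)
#'
#' The channels are split into `g` groups of `C/g`. Per group: horizontal and
#' vertical average pooling condense the width and height axes; the pooled
#' profiles are concatenated and mixed by a shared 1x1 convolution (no
#' channel reduction), and its split outputs gate the group through sigmoids
#' in each direction. A parallel 3x3 convolution enriches local context.
#' Cross-spatial interaction then couples the two paths: the
#' softmax-normalised global-average descriptor of each path weights the
#' spatial map of the other via matrix multiplication, and the summed
#' interaction passes through a sigmoid to reweight the group. Output shape
#' equals input shape.
#'
#' @param f Feature map `(C, H, W)`.
#' @param p An [ema_params()] with matching `C`.
#' @return Feature map `(C, H, W)`.
#' @export
ema_attention <- function(f, p) {
  f <- as_feature_map(f)
  d <- dim(f)
  if (d[1] != p$channels)
    stop(sprintf("EMA params built for %d channels, input has %d",
                 p$channels, d[1]), call. = FALSE)
  cg <- p$cg
  out <- array(0, d)
  for (g in seq_len(p$groups)) {
    idx <- (g - 1L) * cg + seq_len(cg)
    xg <- f[idx, , , drop = FALSE]
    # directional pooling: (cg, H) and (cg, W)
    xh <- apply(xg, c(1, 2), mean)
    xw <- apply(xg, c(1, 3), mean)
    if (cg == 1L) { xh <- matrix(xh, 1L); xw <- matrix(xw, 1L) }
    pooled <- cbind(xh, xw)                      # (cg, H + W)
    mixed <- p$w1 %*% pooled + p$b1              # shared 1x1 over channels
    gh <- sigmoid(mixed[, seq_len(d[2]), drop = FALSE])
    gw <- sigmoid(mixed[, d[2] + seq_len(d[3]), drop = FALSE])
    x1 <- xg
    for (c in seq_len(cg))
      x1[c, , ] <- xg[c, , ] * outer(gh[c, ], gw[c, ])
    # edge-replicated padding keeps the local branch spatially unbiased
    # (a constant input then yields a constant attention map)
    xp <- xg[, c(1, seq_len(d[2]), d[2]), c(1, seq_len(d[3]), d[3]),
             drop = FALSE]
    x2 <- conv2d(xp, p$w3, p$b3, pad = c(0L, 0L))
    # cross-spatial interaction
    m1 <- matrix(x1, cg, d[2] * d[3])
    m2 <- matrix(x2, cg, d[2] * d[3])
    a1 <- softmax(rowMeans(m1))
    a2 <- softmax(rowMeans(m2))
    wsp <- sigmoid(as.numeric(a1 %*% m2) + as.numeric(a2 %*% m1))
    wmat <- matrix(wsp, d[2], d[3])
    for (c in seq_len(cg))
      out[idx[c], , ] <- xg[c, , ] * wmat
  }
  out
}

#' Hard sigmoid
#'
#' `max(0, min(1, (x + 1) / 2))`: the piecewise-linear squashing used by the
#' scale-aware stage of the dynamic detection head. Monotone nondecreasing
#' with range exactly `[0, 1]`.
#'
#' @param x Numeric vector or array.
#' @return Values in `[0, 1]`, same shape as `x`.
#' @export
hard_sigmoid <- function(x) pmax(0, pmin(1, (x + 1) / 2))

#' Parameters of the dynamic detection head block
#'
#' @param channels Shared channel count of all pyramid levels.
#' @param reduction Channel reduction of the task-aware controller (default 4).
#' @param init `"random"` or `"zeros"`.
#' @param scale_weight,scale_bias Scale-aware 1x1 controller: weight vector
#'   (length `C`) and scalar bias; defaults give weight 1 pre-activation
#'   (i.e. `hard_sigmoid(1) = 1`, the identity scale stage) when `init =
#'   "zeros"`.
#' @param spatial_weight Spatial 3x3 sampling kernel `(C, C, 3, 3)`.
#' @param spatial_bias Length-`C` bias of the spatial stage.
#' @param offsets Either `NULL` (zero offsets, unit importance), or a function
#'   `(level_index, H, W)` returning a list with `dy`, `dx`
#'   `(9, H, W)` arrays of sampling offsets and `mask` `(9, H, W)` importance
#'   weights.
#' @param task_alpha_beta Either `NULL` (use the learned theta controller) or
#'   a `C x 4` matrix of fixed `(alpha1, beta1, alpha2, beta2)` rows.
#' @return A list of class `"dyhead_params"`.
#' @export
dyhead_params <- function(channels, reduction = 4L, init = "random",
                          scale_weight = NULL, scale_bias = NULL,
                          spatial_weight = NULL, spatial_bias = NULL,
                          offsets = NULL, task_alpha_beta = NULL) {
  cr <- max(1L, channels %/% reduction)
  rnd <- function(n, fan) if (init == "zeros") numeric(n)
         else stats::rnorm(n) / sqrt(fan)
  structure(list(
    channels = channels,
    scale_weight = if (is.null(scale_weight)) rnd(channels, channels)
                   else scale_weight,
    scale_bias = if (is.null(scale_bias)) {
      if (init == "zeros") 1 else 0
    } else scale_bias,
    spatial_weight = if (is.null(spatial_weight))
      array(rnd(9 * channels^2, 9 * channels), c(channels, channels, 3L, 3L))
      else spatial_weight,
    spatial_bias = if (is.null(spatial_bias)) numeric(channels)
                   else spatial_bias,
    offsets = offsets,
    theta_w1 = matrix(rnd(cr * channels, channels), cr, channels),
    theta_b1 = numeric(cr),
    theta_w2 = matrix(rnd(4L * channels * cr, cr), 4L * channels, cr),
    theta_b2 = numeric(4L * channels),
    task_alpha_beta = task_alpha_beta
  ), class = "dyhead_params")
}

# Bilinear resize of a (C, H, W) feature map to (C, Ho, Wo).
resize_bilinear <- function(f, Ho, Wo) {
  d <- dim(f)
  if (d[2] == Ho && d[3] == Wo) return(f)
  ys <- (seq_len(Ho) - 0.5) * d[2] / Ho + 0.5
  xs <- (seq_len(Wo) - 0.5) * d[3] / Wo + 0.5
  y0 <- pmin(pmax(floor(ys), 1), d[2]); y1 <- pmin(y0 + 1, d[2])
  x0 <- pmin(pmax(floor(xs), 1), d[3]); x1 <- pmin(x0 + 1, d[3])
  wy <- pmin(pmax(ys - y0, 0), 1); wx <- pmin(pmax(xs - x0, 0), 1)
  out <- array(0, c(d[1], Ho, Wo))
  for (c in seq_len(d[1])) {
    m <- f[c, , ]
    out[c, , ] <- (1 - wy) * ((m[y0, x0, drop = FALSE] * rep(1 - wx, each = Ho)) +
                              (m[y0, x1, drop = FALSE] * rep(wx, each = Ho))) +
                  wy * ((m[y1, x0, drop = FALSE] * rep(1 - wx, each = Ho)) +
                        (m[y1, x1, drop = FALSE] * rep(wx, each = Ho)))
  }
  out
}

# Bilinear lookup of channel c at continuous position (y, x), zero outside.
bilinear_at <- function(m, y, x) {
  H <- nrow(m); W <- ncol(m)
  if (y < 1 - 1e-9 || y > H + 1e-9 || x < 1 - 1e-9 || x > W + 1e-9) {
    y0 <- floor(y); x0 <- floor(x)
    v <- 0
    for (yy in c(y0, y0 + 1)) for (xx in c(x0, x0 + 1)) {
      if (yy >= 1 && yy <= H && xx >= 1 && xx <= W)
        v <- v + m[yy, xx] * (1 - abs(y - yy)) * (1 - abs(x - xx))
    }
    return(v)
  }
  y0 <- min(max(floor(y), 1), H); y1 <- min(y0 + 1, H)
  x0 <- min(max(floor(x), 1), W); x1 <- min(x0 + 1, W)
  fy <- y - y0; fx <- x - x0
  m[y0, x0] * (1 - fy) * (1 - fx) + m[y0, x1] * (1 - fy) * fx +
    m[y1, x0] * fy * (1 - fx) + m[y1, x1] * fy * fx
}

#' Dynamic detection head block (scale-, spatial- and task-aware attention)
#'
#' Applies three attentions in order to a feature pyramid whose levels share
#' a channel count:
#'
#' * **Scale-aware**: per level, a 1x1 controller on the spatially pooled
#'   descriptor followed by [hard_sigmoid()] yields a level weight that
#'   rescales the whole level, letting the head emphasise the pyramid levels
#'   matching each object's scale.
#' * **Spatial-aware**: deformable 3x3 sampling — learned per-position
#'   offsets displace the nine taps and importance weights rescale them —
#'   followed by the learned mixing kernel; the sampled maps of adjacent
#'   levels are aggregated (bilinearly resized, averaged) at matching
#'   positions. With zero offsets and unit importance on a single level this
#'   reduces to an ordinary 3x3 convolution.
#' * **Task-aware**: per channel, `max(alpha1 * F_c + beta1,
#'   alpha2 * F_c + beta2)` with `(alpha, beta)` produced by a small
#'   controller (global pooling, reduction layer, two fully connected layers
#'   and a shifted sigmoid bounding them in `[-1, 1]`), or supplied fixed.
#'
#' All shapes are preserved.
#'
#' @param pyramid List of feature maps `(C, H_l, W_l)` sharing `C`.
#' @param params A [dyhead_params()].
#' @return List of feature maps with the same shapes as the input.
#' @export
dyhead_block <- function(pyramid, params) {
  if (!is.list(pyramid) || length(pyramid) == 0L)
    stop("pyramid must be a non-empty list of feature maps", call. = FALSE)
  pyramid <- lapply(pyramid, as_feature_map)
  C <- dim(pyramid[[1]])[1]
  if (any(vapply(pyramid, function(f) dim(f)[1], 1L) != C))
    stop("all pyramid levels must share the channel count", call. = FALSE)
  if (C != params$channels)
    stop("dyhead params channel count does not match pyramid", call. = FALSE)
  L <- length(pyramid)

  # scale-aware
  scaled <- lapply(pyramid, function(f) {
    pooled <- apply(f, 1, mean)
    w <- hard_sigmoid(sum(params$scale_weight * pooled) + params$scale_bias)
    f * w
  })

  # spatial-aware: per-level deformable sampling ...
  sampled <- vector("list", L)
  taps <- expand.grid(dy = -1:1, dx = -1:1)
  taps <- taps[order(taps$dy, taps$dx), ]       # row-major over the 3x3 taps
  for (l in seq_len(L)) {
    f <- scaled[[l]]
    d <- dim(f)
    off <- if (is.null(params$offsets)) NULL
           else params$offsets(l, d[2], d[3])
    shifted <- array(0, c(C, d[2], d[3]))
    # gather the 9 (possibly offset) taps for each input channel, then mix
    tapstack <- array(0, c(9L, C, d[2], d[3]))
    for (k in 1:9) {
      dy <- taps$dy[k]; dx <- taps$dx[k]
      if (is.null(off)) {
        ys <- seq_len(d[2]) + dy; xs <- seq_len(d[3]) + dx
        ok_y <- ys >= 1 & ys <= d[2]; ok_x <- xs >= 1 & xs <= d[3]
        for (c in seq_len(C)) {
          m <- matrix(0, d[2], d[3])
          m[ok_y, ok_x] <- f[c, ys[ok_y], xs[ok_x]]
          tapstack[k, c, , ] <- m
        }
      } else {
        for (c in seq_len(C)) {
          m <- f[c, , ]
          for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
            tapstack[k, c, y, x] <- off$mask[k, y, x] *
              bilinear_at(m, y + dy + off$dy[k, y, x],
                          x + dx + off$dx[k, y, x])
          }
        }
      }
    }
    for (o in seq_len(C)) {
      acc <- matrix(0, d[2], d[3])
      for (k in 1:9) {
        ki <- taps$dy[k] + 2L; kj <- taps$dx[k] + 2L
        for (c in seq_len(C)) {
          w <- params$spatial_weight[o, c, ki, kj]
          if (w != 0) acc <- acc + w * tapstack[k, c, , ]
        }
      }
      shifted[o, , ] <- acc + params$spatial_bias[o]
    }
    sampled[[l]] <- shifted
  }
  # ... aggregated across adjacent levels at matching positions
  spatial <- vector("list", L)
  for (l in seq_len(L)) {
    adj <- intersect(c(l - 1L, l, l + 1L), seq_len(L))
    d <- dim(sampled[[l]])
    acc <- array(0, d)
    for (l2 in adj) acc <- acc + resize_bilinear(sampled[[l2]], d[2], d[3])
    spatial[[l]] <- acc / length(adj)
  }

  # task-aware
  ab <- params$task_alpha_beta
  if (is.null(ab)) {
    pooled <- rowMeans(vapply(spatial, function(f) apply(f, 1, mean),
                              numeric(C)))
    hidden <- pmax(params$theta_w1 %*% pooled + params$theta_b1, 0)
    raw <- as.numeric(params$theta_w2 %*% hidden + params$theta_b2)
    raw <- (raw - mean(raw)) / (stats::sd(raw) + 1e-6)
    bounded <- 2 * sigmoid(raw) - 1            # shifted sigmoid, [-1, 1]
    ab <- matrix(bounded, C, 4L, byrow = FALSE)
  } else {
    if (is.null(dim(ab))) ab <- matrix(ab, C, 4L, byrow = TRUE)
  }
  lapply(spatial, function(f) {
    for (c in seq_len(C)) {
      fc <- f[c, , ]
      f[c, , ] <- pmax(ab[c, 1] * fc + ab[c, 2], ab[c, 3] * fc + ab[c, 4])
    }
    f
  })
}
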