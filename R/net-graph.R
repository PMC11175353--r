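#' @name net_graph
#' @title Detector graph construction and parameter accounting
#'
#' @description
#' Builds the (untrained) single-stage detector graph for a requested variant
#' and accounts for every scalar parameter, layer by layer. The baseline is
#' the stock YOLOv8-nano topology (width multiple 0.25, depth multiple 0.33);
#' the modified variants cumulatively swap stride-2 3x3 downsampling
#' convolutions for space-to-depth convolutions, append a multi-scale
#' convolutional attention block at the bottom of the backbone, add an extra
#' 160x160 small-target detection level, route the head inputs through a
#' dynamic detection head, and insert efficient multi-scale attention blocks
#' after the neck's upsample+concat fusions.
#'
#' Parameter conventions: a convolution block is a bias-free convolution
#' followed by batch normalisation (`cin*cout*k^2 + 2*cout` parameters); the
#' final per-branch 1x1 convolutions of the detection head carry a bias and
#' no normalisation; the head's 16 frozen distribution-focal-loss projection
#' weights are counted as model parameters.
NULL

pc_conv <- function(cin, cout, k = 3L) cin * cout * k^2 + 2L * cout

pc_c2f <- function(cin, cout, n = 1L) {
  c <- cout %/% 2L
  pc_conv(cin, 2L * c, 1L) + pc_conv((2L + n) * c, cout, 1L) +
    n * 2L * pc_conv(c, c, 3L)
}

pc_sppf <- function(cin, cout) {
  c <- cin %/% 2L
  pc_conv(cin, c, 1L) + pc_conv(4L * c, cout, 1L)
}

pc_detect <- function(nc, ch, reg_max = 16L, ch_ref = NULL) {
  # branch widths follow the finest baseline level (P3); when an extra
  # high-resolution level is added it reuses that width instead of shrinking
  # every branch
  if (is.null(ch_ref)) ch_ref <- ch[1]
  c2 <- max(16L, ch_ref %/% 4L, reg_max * 4L)
  c3 <- max(ch_ref, min(nc, 100L))
  box <- sum(vapply(ch, function(ci) {
    pc_conv(ci, c2, 3L) + pc_conv(c2, c2, 3L) +
      (c2 * 4L * reg_max + 4L * reg_max)
  }, 1))
  cls <- sum(vapply(ch, function(ci) {
    pc_conv(ci, c3, 3L) + pc_conv(c3, c3, 3L) + (c3 * nc + nc)
  }, 1))
  box + cls + reg_max          # + frozen DFL projection
}

pc_spdconv <- function(cin, cout, scale = 2L, k = 3L)
  pc_conv(cin * scale^2, cout, k)

pc_msca <- function(C, ks = c(7L, 11L, 21L), base_k = 5L) {
  (C * base_k^2 + C) + sum(2L * (ks * C + C)) + (C^2 + C)
}

pc_ema <- function(C, g = 4L) {
  cg <- C %/% g
  (cg^2 + cg) + (9L * cg^2 + cg)
}

pc_dyhead <- function(C, reduction = 4L) {
  cr <- max(1L, C %/% reduction)
  scale <- C + 1L
  spatial <- (C * 27L * 9L + 27L) + (9L * C^2 + C)   # offset conv + mixing
  task <- (C * cr + cr) + (cr * 4L * C + 4L * C)
  scale + spatial + task
}

#' Architecture configuration
#'
#' @param variant One of `"baseline"`, `"+spdconv"`, `"+attention"`,
#'   `"+stdl"`, `"+dyhead"`, `"full"`. Variants are cumulative in that order:
#'   `"+attention"` includes the space-to-depth convolutions, and `"full"`
#'   includes everything plus the efficient multi-scale attention blocks.
#' @param nc Number of object classes (default 3: sperm, cluster, small or
#'   pinhead).
#' @param imgsz Square input size in pixels (default 640).
#' @return A list of class `"arch_config"`.
#' @export
arch_config <- function(variant = "baseline", nc = 3L, imgsz = 640L) {
  variants <- c("baseline", "+spdconv", "+attention", "+stdl", "+dyhead",
                "full")
  if (!variant %in% variants)
    stop(sprintf("unknown variant '%s'; expected one of %s", variant,
                 paste(variants, collapse = ", ")), call. = FALSE)
  if (nc < 1L) stop("class count must be at least 1", call. = FALSE)
  if (imgsz %% 32L != 0L)
    stop("input size must be a multiple of 32", call. = FALSE)
  structure(list(variant = variant, nc = as.integer(nc),
                 imgsz = as.integer(imgsz),
                 rank = match(variant, variants)),
            class = "arch_config")
}

#' Build the detector graph for a variant
#'
#' Constructs the layer list of the requested variant, propagating feature
#' shapes from a `3 x imgsz x imgsz` input and accounting for every
#' parameter. No weights are instantiated; the graph is the topology plus
#' shape and parameter metadata. The loss configuration plays no role here:
#' changing the regression loss never changes the parameter count.
#'
#' @param cfg An [arch_config()].
#' @return An object of class `"model_graph"`: a list with `variant`, `nc`,
#'   `imgsz`, `layers` (each layer a list with `name`, `type` and `params`
#'   plus an `out` shape `c(C, H, W)`) and `head_levels` (the `(C, H, W)`
#'   shape of each detection level, finest first).
#' @examples
#' g <- build_detector_graph(arch_config("baseline", nc = 3))
#' count_parameters(g)
#' @export
build_detector_graph <- function(cfg) {
  if (!inherits(cfg, "arch_config")) stop("cfg must be an arch_config()",
                                          call. = FALSE)
  rank <- cfg$rank
  use_spd <- rank >= 2L
  use_msca <- rank >= 3L
  use_stdl <- rank >= 4L
  use_dyhead <- rank >= 5L
  use_ema <- rank >= 6L

  layers <- list()
  shapes <- list()
  idx <- 0L
  add <- function(name, type, params, out) {
    idx <<- idx + 1L
    layers[[idx]] <<- list(name = name, type = type, params = params,
                           out = out)
    shapes[[idx]] <<- out
    idx
  }
  down <- function(from, cout, tag) {
    s <- shapes[[from]]
    if (use_spd)
      add(paste0("spdconv_", tag), "spdconv", pc_spdconv(s[1], cout),
          c(cout, s[2] %/% 2L, s[3] %/% 2L))
    else
      add(paste0("conv_", tag), "conv", pc_conv(s[1], cout, 3L),
          c(cout, s[2] %/% 2L, s[3] %/% 2L))
  }
  c2f <- function(from, cout, n, tag) {
    s <- shapes[[from]]
    add(paste0("c2f_", tag), "c2f", pc_c2f(s[1], cout, n),
        c(cout, s[2], s[3]))
  }
  upcat <- function(from, with, tag) {
    s <- shapes[[from]]; sw <- shapes[[with]]
    up <- add(paste0("upsample_", tag), "upsample", 0L,
              c(s[1], s[2] * 2L, s[3] * 2L))
    cat_out <- c(s[1] + sw[1], s[2] * 2L, s[3] * 2L)
    cc <- add(paste0("concat_", tag), "concat", 0L, cat_out)
    if (use_ema)
      cc <- add(paste0("ema_", tag), "ema", pc_ema(cat_out[1]), cat_out)
    cc
  }

  sz <- cfg$imgsz
  # backbone (widths are the nano multiples of 64..1024)
  stem <- if (use_spd && FALSE) NULL else NULL  # stem stays a strided conv
  l0 <- add("conv_stem", "conv", pc_conv(3L, 16L, 3L),
            c(16L, sz %/% 2L, sz %/% 2L))
  l1 <- down(l0, 32L, "p2")
  l2 <- c2f(l1, 32L, 1L, "p2")                       # 160x160 feature
  l3 <- down(l2, 64L, "p3")
  l4 <- c2f(l3, 64L, 2L, "p3")                       # 80x80
  l5 <- down(l4, 128L, "p4")
  l6 <- c2f(l5, 128L, 2L, "p4")                      # 40x40
  l7 <- down(l6, 256L, "p5")
  l8 <- c2f(l7, 256L, 1L, "p5")                      # 20x20
  l9 <- add("sppf", "sppf", pc_sppf(256L, 256L), shapes[[l8]])
  bb_top <- l9
  if (use_msca)
    bb_top <- add("msca_backbone", "msca", pc_msca(256L), shapes[[l9]])

  # neck: top-down
  f4 <- upcat(bb_top, l6, "p4")
  n4 <- c2f(f4, 128L, 1L, "neck_p4")
  f3 <- upcat(n4, l4, "p3")
  n3 <- c2f(f3, 64L, 1L, "neck_p3")
  if (use_stdl) {
    f2 <- upcat(n3, l2, "p2")
    n2 <- c2f(f2, 32L, 1L, "neck_p2")                # 160x160 head level
    d3 <- down(n2, 32L, "pan_p3")
    cat3 <- add("concat_pan_p3", "concat", 0L,
                c(32L + 64L, shapes[[n3]][2], shapes[[n3]][3]))
    p3 <- c2f(cat3, 64L, 1L, "pan_p3")
  } else {
    n2 <- NULL
    p3 <- n3
  }
  d4 <- down(p3, 64L, "pan_p4")
  cat4 <- add("concat_pan_p4", "concat", 0L,
              c(64L + 128L, shapes[[n4]][2], shapes[[n4]][3]))
  p4 <- c2f(cat4, 128L, 1L, "pan_p4")
  d5 <- down(p4, 128L, "pan_p5")
  cat5 <- add("concat_pan_p5", "concat", 0L,
              c(128L + 256L, shapes[[bb_top]][2], shapes[[bb_top]][3]))
  p5 <- c2f(cat5, 256L, 1L, "pan_p5")

  head_in <- if (use_stdl) c(n2, p3, p4, p5) else c(p3, p4, p5)
  ch <- vapply(head_in, function(i) shapes[[i]][1], 1L)

  if (use_dyhead) {
    cu <- 128L
    for (i in seq_along(head_in)) {
      s <- shapes[[head_in[i]]]
      head_in[i] <- add(paste0("head_unify_", i), "conv",
                        pc_conv(s[1], cu, 1L), c(cu, s[2], s[3]))
    }
    add("dyhead", "dyhead", pc_dyhead(cu),
        shapes[[head_in[length(head_in)]]])
    ch <- rep(cu, length(head_in))
  }

  ch_ref <- if (use_stdl && !use_dyhead) ch[2] else ch[1]
  add("detect", "detect", pc_detect(cfg$nc, ch, ch_ref = ch_ref),
      c(sum(ch), 0L, 0L))

  structure(list(
    variant = cfg$variant, nc = cfg$nc, imgsz = cfg$imgsz,
    layers = layers,
    head_levels = lapply(head_in, function(i) shapes[[i]])
  ), class = "model_graph")
}

#' Count the parameters of a detector graph
#'
#' Sums the scalar parameters of every layer, including the head's 16 frozen
#' distribution-focal-loss projection weights (the convention of the standard
#' tooling's parameter summaries).
#'
#' @param g A `"model_graph"` from [build_detector_graph()], or any list with
#'   a `layers` element whose entries carry a `params` count.
#' @return Integer parameter count (0 for an empty graph).
#' @export
count_parameters <- function(g) {
  if (is.null(g$layers) || length(g$layers) == 0L) return(0L)
  sum(vapply(g$layers, function(l) as.numeric(l$params), 1))
}

#' @export
print.model_graph <- function(x, ...) {
  cat(sprintf("<model_graph variant=%s nc=%d imgsz=%d>\n",
              x$variant, x$nc, x$imgsz))
  for (l in x$layers)
    cat(sprintf("  %-18s %-9s params=%9d  out=%s\n", l$name, l$type,
                as.integer(l$params),
                paste(l$out, collapse = "x")))
  cat(sprintf("head levels: %s\n",
              paste(vapply(x$head_levels,
                           function(s) paste(s, collapse = "x"), ""),
                    collapse = ", ")))
  cat(sprintf("total parameters: %d\n", as.integer(count_parameters(x))))
  invisible(x)
}
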