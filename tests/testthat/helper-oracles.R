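# Independent oracles used across the suite. These deliberately avoid the
# package's code paths: IoU by subpixel rasterisation, the Gaussian
# 2-Wasserstein distance in its general matrix form, assignment by
# exhaustive enumeration, CLEAR/ID metrics by brute-force matching, and the
# attention operators as literal loops.

# IoU by counting subpixel cells (separable: count per axis, multiply).
raster_iou <- function(a, b, res = 0.01) {
  lo_x <- min(a[1], b[1]); hi_x <- max(a[3], b[3])
  lo_y <- min(a[2], b[2]); hi_y <- max(a[4], b[4])
  xs <- seq(lo_x + res / 2, hi_x, by = res)
  ys <- seq(lo_y + res / 2, hi_y, by = res)
  in_ax <- xs > a[1] & xs < a[3]; in_bx <- xs > b[1] & xs < b[3]
  in_ay <- ys > a[2] & ys < a[4]; in_by <- ys > b[2] & ys < b[4]
  inter <- sum(in_ax & in_bx) * sum(in_ay & in_by)
  union <- sum(in_ax) * sum(in_ay) + sum(in_bx) * sum(in_by) - inter
  inter / union
}

# General closed-form squared 2-Wasserstein distance between Gaussians:
# ||m1 - m2||^2 + tr(S1 + S2 - 2 (S2^1/2 S1 S2^1/2)^1/2).
gauss_w2sq_ref <- function(m1, S1, m2, S2) {
  msqrt <- function(S) {
    e <- eigen(S, symmetric = TRUE)
    e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(S)) %*% t(e$vectors)
  }
  R2 <- msqrt(S2)
  cross <- msqrt(R2 %*% S1 %*% R2)
  sum((m1 - m2)^2) + sum(diag(S1 + S2 - 2 * cross))
}

# Exhaustive minimum-cost assignment over all injections (rows into columns
# or vice versa); Inf-cost pairs are infeasible. Returns the best total over
# assignments of maximum feasible cardinality.
perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}

brute_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  best_cost <- Inf; best_k <- -1L
  if (n <= m) {
    for (p in perms(seq_len(m))) {
      v <- cost[cbind(seq_len(n), p[seq_len(n)])]
      k <- sum(is.finite(v)); s <- sum(v[is.finite(v)])
      if (k > best_k || (k == best_k && s < best_cost)) {
        best_k <- k; best_cost <- s
      }
    }
  } else {
    for (p in perms(seq_len(n))) {
      v <- cost[cbind(p[seq_len(m)], seq_len(m))]
      k <- sum(is.finite(v)); s <- sum(v[is.finite(v)])
      if (k > best_k || (k == best_k && s < best_cost)) {
        best_k <- k; best_cost <- s
      }
    }
  }
  list(cost = best_cost, k = best_k)
}

scalar_iou <- function(a, b) {
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  inter / ((a[3] - a[1]) * (a[4] - a[2]) +
           (b[3] - b[1]) * (b[4] - b[2]) - inter)
}

# Reference CLEAR metrics by exhaustive per-frame matching with the same
# continuity convention (a ground truth keeps its previous partner while
# the pairing clears the threshold).
ref_mota_idf1 <- function(gt, pred, thr = 0.5) {
  frames <- sort(unique(c(gt$frame, pred$frame)))
  gids <- sort(unique(gt$id)); pids <- sort(unique(pred$id))
  last <- stats::setNames(rep(NA_integer_, length(gids)), gids)
  co <- matrix(0L, length(gids), length(pids))
  FN <- FP <- IDSW <- 0L
  box_of <- function(df, i) as.numeric(df[i, c("x1", "y1", "x2", "y2")])
  for (f in frames) {
    G <- gt[gt$frame == f, , drop = FALSE]
    P <- pred[pred$frame == f, , drop = FALSE]
    nG <- nrow(G); nP <- nrow(P)
    if (nG && nP) {
      iou <- matrix(0, nG, nP)
      for (i in seq_len(nG)) for (j in seq_len(nP))
        iou[i, j] <- scalar_iou(box_of(G, i), box_of(P, j))
      # co-occurrence for the ID metrics (threshold only, no matching)
      hit <- which(iou >= thr, arr.ind = TRUE)
      if (nrow(hit))
        for (r in seq_len(nrow(hit)))
          co[match(G$id[hit[r, 1]], gids), match(P$id[hit[r, 2]], pids)] <-
            co[match(G$id[hit[r, 1]], gids), match(P$id[hit[r, 2]], pids)] + 1L
      # continuity
      mg <- integer(0); mp <- integer(0)
      for (i in seq_len(nG)) {
        lp <- last[as.character(G$id[i])]
        j <- match(lp, P$id)
        if (!is.na(lp) && !is.na(j) && !(j %in% mp) && iou[i, j] >= thr) {
          mg <- c(mg, i); mp <- c(mp, j)
        }
      }
      rg <- setdiff(seq_len(nG), mg); rp <- setdiff(seq_len(nP), mp)
      if (length(rg) && length(rp)) {
        sub <- iou[rg, rp, drop = FALSE]
        sub[sub < thr] <- NA
        best <- NULL; best_k <- -1L; best_s <- -Inf
        kmax <- min(length(rg), length(rp))
        assignments <- function(gs, taken, acc) {
          if (!length(gs)) {
            k <- nrow(acc)
            s <- if (k) sum(sub[acc]) else 0
            if (k > best_k || (k == best_k && s > best_s)) {
              best_k <<- k; best_s <<- s; best <<- acc
            }
            return()
          }
          g1 <- gs[1]
          assignments(gs[-1], taken, acc)        # leave g1 unmatched
          for (p1 in setdiff(seq_along(rp), taken)) {
            if (!is.na(sub[g1, p1]))
              assignments(gs[-1], c(taken, p1), rbind(acc, c(g1, p1)))
          }
        }
        assignments(seq_along(rg), integer(0), matrix(0L, 0L, 2L))
        if (!is.null(best) && nrow(best)) {
          mg <- c(mg, rg[best[, 1]]); mp <- c(mp, rp[best[, 2]])
        }
      }
      FN <- FN + nG - length(mg)
      FP <- FP + nP - length(mp)
      for (k in seq_along(mg)) {
        gidc <- as.character(G$id[mg[k]])
        pid <- P$id[mp[k]]
        if (!is.na(last[gidc]) && last[gidc] != pid) IDSW <- IDSW + 1L
        last[gidc] <- pid
      }
    } else {
      FN <- FN + nG; FP <- FP + nP
    }
  }
  mota <- (1 - (FN + FP + IDSW) / nrow(gt)) * 100
  # IDF1: exhaustive injective map from gt ids to pred ids (or none)
  # maximising total co-occurrence; enumerated over the gt side
  idtp <- 0L
  if (length(pids) && length(gids)) {
    recurse <- function(g, taken, acc) {
      if (g > length(gids)) { if (acc > idtp) idtp <<- acc; return() }
      recurse(g + 1L, taken, acc)                 # gt id left unmatched
      for (p in setdiff(seq_along(pids), taken))
        if (co[g, p] > 0L) recurse(g + 1L, c(taken, p), acc + co[g, p])
    }
    recurse(1L, integer(0), 0L)
  }
  idf1 <- 2 * idtp / (2 * idtp + (nrow(pred) - idtp) + (nrow(gt) - idtp)) * 100
  list(MOTA = mota, IDF1 = idf1, IDSW = IDSW, FN = FN, FP = FP)
}

# literal loop implementations of the tensor operators -----------------------

naive_conv2d <- function(f, weight, bias = NULL) {
  d <- dim(f); wd <- dim(weight)
  ph <- (wd[3] - 1) %/% 2; pw <- (wd[4] - 1) %/% 2
  out <- array(0, c(wd[1], d[2], d[3]))
  for (o in seq_len(wd[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    acc <- 0
    for (i in seq_len(d[1])) for (ky in seq_len(wd[3])) for (kx in seq_len(wd[4])) {
      yy <- y + ky - 1 - ph; xx <- x + kx - 1 - pw
      if (yy >= 1 && yy <= d[2] && xx >= 1 && xx <= d[3])
        acc <- acc + weight[o, i, ky, kx] * f[i, yy, xx]
    }
    out[o, y, x] <- acc + if (is.null(bias)) 0 else bias[o]
  }
  out
}

naive_dwconv <- function(f, weight, bias = NULL) {
  d <- dim(f); wd <- dim(weight)
  out <- array(0, d)
  for (c in seq_len(d[1])) {
    w4 <- array(0, c(1, 1, wd[2], wd[3]))
    w4[1, 1, , ] <- weight[c, , ]
    out[c, , ] <- naive_conv2d(f[c, , , drop = FALSE], w4,
                               if (is.null(bias)) NULL else bias[c])
  }
  out
}

naive_msca <- function(f, p) {
  C <- dim(f)[1]
  u <- naive_dwconv(f, p$base)
  s <- if (p$shortcut) f else array(0, dim(f))
  for (br in p$branches) {
    wh <- array(0, c(C, 1, br$k)); wh[, 1, ] <- br$horiz
    wv <- array(0, c(C, br$k, 1)); wv[, , 1] <- br$vert
    s <- s + naive_dwconv(naive_dwconv(u, wh), wv)
  }
  mix <- array(0, c(C, C, 1, 1)); mix[, , 1, 1] <- p$mix
  att <- naive_conv2d(s, mix, p$mix_bias)
  att * f
}

naive_ema <- function(f, p) {
  d <- dim(f); cg <- p$cg
  sig <- function(x) 1 / (1 + exp(-x))
  out <- array(0, d)
  for (g in seq_len(p$groups)) {
    idx <- (g - 1) * cg + seq_len(cg)
    xg <- f[idx, , , drop = FALSE]
    xh <- matrix(0, cg, d[2]); xw <- matrix(0, cg, d[3])
    for (c in seq_len(cg)) {
      for (y in seq_len(d[2])) xh[c, y] <- mean(xg[c, y, ])
      for (x in seq_len(d[3])) xw[c, x] <- mean(xg[c, , x])
    }
    mixed <- matrix(0, cg, d[2] + d[3])
    pooled <- cbind(xh, xw)
    for (o in seq_len(cg)) for (j in seq_len(d[2] + d[3]))
      mixed[o, j] <- sum(p$w1[o, ] * pooled[, j]) + p$b1[o]
    x1 <- xg
    for (c in seq_len(cg)) for (y in seq_len(d[2])) for (x in seq_len(d[3]))
      x1[c, y, x] <- xg[c, y, x] * sig(mixed[c, y]) * sig(mixed[c, d[2] + x])
    # edge-replicated padding, mirroring the operator's local branch
    d2 <- dim(xg)
    xp <- array(0, c(cg, d2[2] + 2, d2[3] + 2))
    for (c in seq_len(cg)) for (y in 0:(d2[2] + 1)) for (x in 0:(d2[3] + 1))
      xp[c, y + 1, x + 1] <- xg[c, min(max(y, 1), d2[2]),
                                min(max(x, 1), d2[3])]
    x2full <- naive_conv2d(xp, p$w3, p$b3)
    x2 <- x2full[, 2:(d2[2] + 1), 2:(d2[3] + 1), drop = FALSE]
    gap1 <- apply(x1, 1, mean); gap2 <- apply(x2, 1, mean)
    a1 <- exp(gap1 - max(gap1)); a1 <- a1 / sum(a1)
    a2 <- exp(gap2 - max(gap2)); a2 <- a2 / sum(a2)
    for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
      t1 <- sum(a1 * x2[, y, x]); t2 <- sum(a2 * x1[, y, x])
      w <- sig(t1 + t2)
      for (c in seq_len(cg)) out[idx[c], y, x] <- xg[c, y, x] * w
    }
  }
  out
}

# random valid box within a width x height frame
random_box <- function(width = 640, height = 480, min_size = 2,
                       max_size = 40) {
  w <- stats::runif(1, min_size, max_size)
  h <- stats::runif(1, min_size, max_size)
  x1 <- stats::runif(1, 0, width - w)
  y1 <- stats::runif(1, 0, height - h)
  c(x1, y1, x1 + w, y1 + h)
}
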