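#' Minimum-cost one-to-one assignment (Hungarian algorithm)
#'
#' Solves the rectangular linear assignment problem by the shortest
#' augmenting path formulation of the Hungarian method (Jonker-Volgenant
#' style, O(n^3)). Entries of `Inf` mark forbidden pairings; the matrix is
#' padded to square internally, so with `n` rows and `m` columns at most
#' `min(n, m)` feasible pairs are returned.
#'
#' @param cost Numeric matrix of pairwise costs; `Inf` forbids a pairing.
#' @return A list with `rows` and `cols` (parallel integer vectors of matched
#'   row/column indices) and `cost`, the summed cost of the returned matches.
#' @examples
#' solve_assignment(matrix(c(4, 2, 8, 4, 3, 7, 3, 1, 6), 3, 3))
#' @export
solve_assignment <- function(cost) {
  if (!is.matrix(cost)) cost <- as.matrix(cost)
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L || m == 0L)
    return(list(rows = integer(0), cols = integer(0), cost = 0))
  if (any(is.na(cost)) || any(cost == -Inf))
    stop("cost matrix must be free of NA/-Inf", call. = FALSE)
  N <- max(n, m)
  finite <- cost[is.finite(cost)]
  big <- if (length(finite)) sum(abs(finite)) + max(abs(finite)) + 1 else 1
  C <- matrix(big, N, N)
  C[seq_len(n), seq_len(m)] <- ifelse(is.finite(cost), cost, big)

  # columns indexed 0..N with 0 a sentinel; stored at offset +1
  u <- numeric(N + 1)
  v <- numeric(N + 1)
  p <- integer(N + 1)    # p[j + 1]: row assigned to column j (0 = none)
  way <- integer(N + 1)
  js <- seq_len(N)
  for (i in seq_len(N)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, N)
    used <- rep(FALSE, N + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free <- js[!used[js + 1L]]
      cur <- C[i0, free] - u[i0] - v[free + 1L]
      upd <- cur < minv[free]
      if (any(upd)) {
        minv[free[upd]] <- cur[upd]
        way[free[upd] + 1L] <- j0
      }
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      usedj <- which(used) - 1L          # actual column ids incl. sentinel
      u[p[usedj + 1L]] <- u[p[usedj + 1L]] + delta
      v[usedj + 1L] <- v[usedj + 1L] - delta
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }

  rows <- integer(0); cols <- integer(0)
  for (j in seq_len(N)) {
    i <- p[j + 1L]
    if (i >= 1L && i <= n && j <= m && is.finite(cost[i, j])) {
      rows <- c(rows, i); cols <- c(cols, j)
    }
  }
  list(rows = rows, cols = cols,
       cost = if (length(rows)) sum(cost[cbind(rows, cols)]) else 0)
}
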