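#' Axis-aligned bounding box
#'
#' Boxes live in continuous pixel coordinates with the origin at the top-left
#' corner, x increasing rightward and y increasing downward. A box is the real
#' rectangle `[x1, x2] x [y1, y2]` (no half-open pixel semantics); both extents
#' must be strictly positive.
#'
#' @param x1,y1 Top-left corner.
#' @param x2,y2 Bottom-right corner; `x2 > x1`, `y2 > y1`.
#' @return A numeric vector `c(x1, y1, x2, y2)` of class `"bbox"`.
#' @examples
#' b <- bbox(0, 0, 2, 2)
#' box_iou(b, bbox(1, 1, 3, 3))
#' @export
bbox <- function(x1, y1, x2, y2) {
  b <- c(x1 = as.numeric(x1), y1 = as.numeric(y1),
         x2 = as.numeric(x2), y2 = as.numeric(y2))
  validate_box(b)
  class(b) <- "bbox"
  b
}

#' @export
print.bbox <- function(x, ...) {
  cat(sprintf("<bbox (%.6g, %.6g) -- (%.6g, %.6g)  w=%.6g h=%.6g>\n",
              x[1], x[2], x[3], x[4], x[3] - x[1], x[4] - x[2]))
  invisible(x)
}

validate_box <- function(b, arg = "box") {
  if (!is.numeric(b) || length(b) != 4L || anyNA(b) || any(!is.finite(b)))
    stop(sprintf("%s must be a finite numeric vector (x1, y1, x2, y2)", arg),
         call. = FALSE)
  if (b[3] <= b[1] || b[4] <= b[2])
    stop(sprintf("degenerate %s: need x2 > x1 and y2 > y1 (got w=%g, h=%g)",
                 arg, b[3] - b[1], b[4] - b[2]), call. = FALSE)
  invisible(b)
}

#' Image size
#'
#' @param w,h Width and height in pixels, strictly positive.
#' @return A numeric vector `c(w, h)` of class `"image_size"`.
#' @export
image_size <- function(w, h) {
  s <- c(w = as.numeric(w), h = as.numeric(h))
  if (anyNA(s) || any(!is.finite(s)) || any(s <= 0))
    stop("image size must have positive finite width and height", call. = FALSE)
  class(s) <- "image_size"
  s
}

box_w <- function(b) b[[3]] - b[[1]]
box_h <- function(b) b[[4]] - b[[2]]
box_cx <- function(b) (b[[1]] + b[[3]]) / 2
box_cy <- function(b) (b[[2]] + b[[4]]) / 2
box_area <- function(b) box_w(b) * box_h(b)

#' Loss configuration for the combined small-object regression loss
#'
#' @param nwd_constant Normalisation constant `C` of the Normalized
#'   Wasserstein Distance, `exp(-W2/C)`. A dataset-scale constant; the default
#'   12.8 is the value in common use for tiny-object benchmarks.
#' @param inner_ratio Scale factor applied about each box's centre to form the
#'   auxiliary boxes of Inner-IoU. Values above 1 enlarge the auxiliary boxes,
#'   sharpening gradients for small targets. Default 1.15.
#' @param iou_ratio Weight in `[0, 1]` blending the Inner-MPDIoU loss (weight
#'   `iou_ratio`) with the NWD loss (weight `1 - iou_ratio`). Default 0.5.
#' @return A list of class `"loss_config"`.
#' @export
loss_config <- function(nwd_constant = 12.8, inner_ratio = 1.15,
                        iou_ratio = 0.5) {
  if (!is.numeric(nwd_constant) || length(nwd_constant) != 1L ||
      !is.finite(nwd_constant) || nwd_constant <= 0)
    stop("nwd_constant must be a positive number", call. = FALSE)
  if (!is.numeric(inner_ratio) || length(inner_ratio) != 1L ||
      !is.finite(inner_ratio) || inner_ratio <= 0)
    stop("inner_ratio must be a positive number", call. = FALSE)
  if (!is.numeric(iou_ratio) || length(iou_ratio) != 1L ||
      !is.finite(iou_ratio) || iou_ratio < 0 || iou_ratio > 1)
    stop("iou_ratio must lie in [0, 1]", call. = FALSE)
  structure(list(nwd_constant = nwd_constant, inner_ratio = inner_ratio,
                 iou_ratio = iou_ratio),
            class = "loss_config")
}

#' Intersection-over-union of two boxes
#'
#' Continuous-geometry IoU: `I / (A_a + A_b - I)` with the intersection area
#' zero when the boxes do not overlap.
#'
#' @param a,b Boxes (`bbox` or numeric `c(x1, y1, x2, y2)`).
#' @return IoU in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  validate_box(a, "a"); validate_box(b, "b")
  inter <- intersection_area(a, b)
  inter / (box_area(a) + box_area(b) - inter)
}

intersection_area <- function(a, b) {
  iw <- min(a[[3]], b[[3]]) - max(a[[1]], b[[1]])
  ih <- min(a[[4]], b[[4]]) - max(a[[2]], b[[2]])
  if (iw > 0 && ih > 0) iw * ih else 0
}

#' Complete IoU (CIoU)
#'
#' IoU minus the squared centre distance normalised by the squared diagonal of
#' the minimum enclosing box, minus the aspect-ratio consistency term
#' `alpha * v`. Provided as the stock-detector baseline comparator for the
#' small-object losses.
#'
#' @inheritParams box_iou
#' @return CIoU value (at most the plain IoU; 1 for identical boxes).
#' @export
box_ciou <- function(a, b) {
  validate_box(a, "a"); validate_box(b, "b")
  iou <- box_iou(a, b)
  # squared diagonal of the minimum enclosing box
  cw <- max(a[[3]], b[[3]]) - min(a[[1]], b[[1]])
  ch <- max(a[[4]], b[[4]]) - min(a[[2]], b[[2]])
  c2 <- cw^2 + ch^2
  rho2 <- (box_cx(a) - box_cx(b))^2 + (box_cy(a) - box_cy(b))^2
  v <- (4 / pi^2) * (atan(box_w(b) / box_h(b)) - atan(box_w(a) / box_h(a)))^2
  alpha <- if (v > 0) v / (1 - iou + v + .Machine$double.eps) else 0
  iou - rho2 / c2 - alpha * v
}

#' Minimum-point-distance IoU (MPDIoU)
#'
#' IoU penalised by the squared distances between the two top-left corners and
#' between the two bottom-right corners, each normalised by `w^2 + h^2` of the
#' input image. Minimising corner distances couples centre alignment and size
#' agreement in a single term.
#'
#' @inheritParams box_iou
#' @param img An [image_size()].
#' @return A value in `[-2, 1]`; 1 iff the boxes are identical.
#' @export
box_mpdiou <- function(a, b, img) {
  validate_box(a, "a"); validate_box(b, "b")
  if (!inherits(img, "image_size")) img <- image_size(img[[1]], img[[2]])
  d1sq <- (a[[1]] - b[[1]])^2 + (a[[2]] - b[[2]])^2
  d2sq <- (a[[3]] - b[[3]])^2 + (a[[4]] - b[[4]])^2
  norm <- img[[1]]^2 + img[[2]]^2
  box_iou(a, b) - d1sq / norm - d2sq / norm
}

#' MPDIoU loss, `1 - MPDIoU`
#'
#' @inheritParams box_mpdiou
#' @return Nonnegative loss; 0 iff the boxes are identical.
#' @export
mpdiou_loss <- function(a, b, img) 1 - box_mpdiou(a, b, img)

#' Inner-IoU: IoU of centre-scaled auxiliary boxes
#'
#' Each box is scaled about its own centre by `ratio` (widths and heights
#' multiplied, centres fixed); the IoU of the two auxiliary boxes is returned,
#' with the union written as `ratio^2 (A_a + A_b) - inter`. `ratio = 1`
#' recovers the plain IoU exactly.
#'
#' @inheritParams box_iou
#' @param ratio Positive scale factor for the auxiliary boxes.
#' @return Inner-IoU value in `[0, 1]`.
#' @export
inner_iou <- function(a, b, ratio) {
  validate_box(a, "a"); validate_box(b, "b")
  if (!is.numeric(ratio) || length(ratio) != 1L || !is.finite(ratio) ||
      ratio <= 0)
    stop("ratio must be a positive number", call. = FALSE)
  sa <- scale_about_center(a, ratio)
  sb <- scale_about_center(b, ratio)
  inter <- intersection_area(sa, sb)
  inter / (ratio^2 * (box_area(a) + box_area(b)) - inter)
}

scale_about_center <- function(b, ratio) {
  cx <- box_cx(b); cy <- box_cy(b)
  hw <- box_w(b) * ratio / 2; hh <- box_h(b) * ratio / 2
  c(cx - hw, cy - hh, cx + hw, cy + hh)
}

#' Inner-MPDIoU loss
#'
#' `L_MPDIoU + IoU - IoU_inner`: the MPDIoU loss with the plain IoU replaced,
#' at the margin, by the auxiliary-box IoU. Since `MPDIoU <= IoU`, the value
#' is at least `1 - IoU_inner >= 0`.
#'
#' @inheritParams box_mpdiou
#' @param ratio Auxiliary-box scale factor (see [inner_iou()]).
#' @return Nonnegative loss; 0 iff the boxes are identical.
#' @export
inner_mpdiou_loss <- function(a, b, img, ratio) {
  mpdiou_loss(a, b, img) + box_iou(a, b) - inner_iou(a, b, ratio)
}

#' Gaussian model of a bounding box
#'
#' A box is modelled as a 2-D Gaussian with mean at the box centre and
#' covariance `diag(w^2/4, h^2/4)`: centre pixels carry the most weight and
#' importance decays toward the edges, which suits tiny objects whose boxes
#' contain background near the borders.
#'
#' @param a A box.
#' @return A list with `mean` (length-2) and `cov` (2x2 diagonal matrix),
#'   class `"gaussian_box"`.
#' @export
gaussian_from_box <- function(a) {
  validate_box(a, "a")
  structure(list(mean = c(box_cx(a), box_cy(a)),
                 cov = diag(c(box_w(a)^2 / 4, box_h(a)^2 / 4))),
            class = "gaussian_box")
}

#' Squared 2-Wasserstein distance between the Gaussian models of two boxes
#'
#' For the diagonal covariances of [gaussian_from_box()] the squared
#' 2-Wasserstein distance collapses to the squared L2 distance between the
#' 4-vectors `[cx, cy, w/2, h/2]`.
#'
#' @inheritParams box_iou
#' @return Nonnegative squared distance; 0 iff the boxes are identical.
#' @export
wasserstein2_sq <- function(a, b) {
  validate_box(a, "a"); validate_box(b, "b")
  (box_cx(a) - box_cx(b))^2 + (box_cy(a) - box_cy(b))^2 +
    (box_w(a) / 2 - box_w(b) / 2)^2 + (box_h(a) / 2 - box_h(b) / 2)^2
}

#' Normalized Wasserstein Distance (NWD) between two boxes
#'
#' `exp(-sqrt(W2^2) / C)`: the exponential normalisation turns the Wasserstein
#' distance into a similarity in `(0, 1]`. Unlike IoU it remains informative
#' when the boxes do not overlap, and it is far less sensitive to small
#' positional deviations of tiny boxes.
#'
#' @inheritParams box_iou
#' @param cfg A [loss_config()], or a single positive number taken as the
#'   constant `C`.
#' @return Similarity in `(0, 1]`; 1 iff the boxes are identical.
#' @export
box_nwd <- function(a, b, cfg = loss_config()) {
  C <- if (inherits(cfg, "loss_config")) cfg$nwd_constant else cfg
  if (!is.numeric(C) || length(C) != 1L || !is.finite(C) || C <= 0)
    stop("the NWD constant C must be positive", call. = FALSE)
  exp(-sqrt(wasserstein2_sq(a, b)) / C)
}

#' Combined small-object bounding-box regression loss
#'
#' The full regression loss for tiny targets:
#' `L = iou_ratio * L_Inner-MPDIoU + (1 - iou_ratio) * L_NWD`, with
#' `L_NWD = 1 - NWD`. Every intermediate quantity is returned so the blend can
#' be inspected term by term.
#'
#' @param prd Predicted box.
#' @param gt Ground-truth box.
#' @param img An [image_size()].
#' @param cfg A [loss_config()].
#' @return A list of class `"loss_breakdown"` with elements `iou`, `ciou`,
#'   `mpdiou`, `L_mpdiou`, `iou_inner`, `L_inner_mpdiou`, `w2_sq`, `nwd`,
#'   `L_nwd`, `L_total`.
#' @examples
#' combined_regression_loss(bbox(0, 0, 2, 2), bbox(1, 1, 3, 3),
#'                          image_size(10, 10))
#' @export
combined_regression_loss <- function(prd, gt, img, cfg = loss_config()) {
  if (!inherits(cfg, "loss_config"))
    stop("cfg must be a loss_config()", call. = FALSE)
  iou <- box_iou(prd, gt)
  mpd <- box_mpdiou(prd, gt, img)
  l_mpd <- 1 - mpd
  iinner <- inner_iou(prd, gt, cfg$inner_ratio)
  l_inner <- l_mpd + iou - iinner
  w2 <- wasserstein2_sq(prd, gt)
  nwd <- exp(-sqrt(w2) / cfg$nwd_constant)
  l_nwd <- 1 - nwd
  structure(list(
    iou = iou,
    ciou = box_ciou(prd, gt),
    mpdiou = mpd,
    L_mpdiou = l_mpd,
    iou_inner = iinner,
    L_inner_mpdiou = l_inner,
    w2_sq = w2,
    nwd = nwd,
    L_nwd = l_nwd,
    L_total = cfg$iou_ratio * l_inner + (1 - cfg$iou_ratio) * l_nwd
  ), class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  for (k in names(x)) cat(sprintf("%s=%.9g\n", k, x[[k]]))
  invisible(x)
}

# Pairwise IoU between two sets of boxes.
# A: n x 4 matrix, B: m x 4 matrix (x1, y1, x2, y2 columns). Returns n x m.
iou_matrix <- function(A, B) {
  if (is.null(dim(A))) A <- matrix(A, ncol = 4L)
  if (is.null(dim(B))) B <- matrix(B, ncol = 4L)
  n <- nrow(A); m <- nrow(B)
  if (n == 0L || m == 0L) return(matrix(0, n, m))
  ix1 <- pmax(matrix(A[, 1], n, m), matrix(B[, 1], n, m, byrow = TRUE))
  iy1 <- pmax(matrix(A[, 2], n, m), matrix(B[, 2], n, m, byrow = TRUE))
  ix2 <- pmin(matrix(A[, 3], n, m), matrix(B[, 3], n, m, byrow = TRUE))
  iy2 <- pmin(matrix(A[, 4], n, m), matrix(B[, 4], n, m, byrow = TRUE))
  inter <- pmax(ix2 - ix1, 0) * pmax(iy2 - iy1, 0)
  areaA <- (A[, 3] - A[, 1]) * (A[, 4] - A[, 2])
  areaB <- (B[, 3] - B[, 1]) * (B[, 4] - B[, 2])
  inter / (matrix(areaA, n, m) + matrix(areaB, n, m, byrow = TRUE) - inter)
}

# Pairwise NWD between two sets of boxes (n x 4, m x 4) -> n x m.
nwd_matrix <- function(A, B, C = 12.8) {
  if (is.null(dim(A))) A <- matrix(A, ncol = 4L)
  if (is.null(dim(B))) B <- matrix(B, ncol = 4L)
  n <- nrow(A); m <- nrow(B)
  if (n == 0L || m == 0L) return(matrix(0, n, m))
  fa <- cbind((A[, 1] + A[, 3]) / 2, (A[, 2] + A[, 4]) / 2,
              (A[, 3] - A[, 1]) / 2, (A[, 4] - A[, 2]) / 2)
  fb <- cbind((B[, 1] + B[, 3]) / 2, (B[, 2] + B[, 4]) / 2,
              (B[, 3] - B[, 1]) / 2, (B[, 4] - B[, 2]) / 2)
  w2 <- outer(rowSums(fa^2), rowSums(fb^2), "+") - 2 * tcrossprod(fa, fb)
  exp(-sqrt(pmax(w2, 0)) / C)
}
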