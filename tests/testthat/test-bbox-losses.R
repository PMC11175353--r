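test_that("IoU matches continuous geometry and the rasterisation oracle", {
  expect_equal(box_iou(bbox(0, 0, 2, 2), bbox(0, 0, 2, 2)), 1)
  expect_equal(box_iou(bbox(0, 0, 2, 2), bbox(5, 5, 7, 7)), 0)
  expect_equal(box_iou(bbox(0, 0, 2, 2), bbox(1, 1, 3, 3)), 1 / 7)
  expect_equal(raster_iou(c(0, 0, 2, 2), c(1, 1, 3, 3)), 1 / 7,
               tolerance = 1e-3)
  set.seed(101)
  for (i in 1:50) {
    a <- round(random_box(20, 20, 4, 12), 2)
    b <- round(random_box(20, 20, 4, 12), 2)
    expect_lt(abs(box_iou(a, b) - raster_iou(a, b)), 1e-3)
  }
})

test_that("degenerate boxes and invalid configs are rejected", {
  expect_error(box_iou(c(0, 0, 0, 2), c(0, 0, 1, 1)), "degenerate")
  expect_error(bbox(1, 1, 1, 3), "degenerate")
  expect_error(image_size(0, 10), "positive")
  expect_error(loss_config(nwd_constant = -1), "positive")
  expect_error(loss_config(iou_ratio = 1.5), "\\[0, 1\\]")
  expect_error(inner_iou(bbox(0, 0, 1, 1), bbox(0, 0, 1, 1), ratio = 0),
               "positive")
  expect_error(box_nwd(bbox(0, 0, 1, 1), bbox(0, 0, 1, 1), cfg = -2),
               "positive")
})

test_that("CIoU agrees with an independent term-by-term recomputation", {
  expect_equal(box_ciou(bbox(0, 0, 2, 2), bbox(0, 0, 2, 2)), 1)
  # concentric, equal aspect ratio: centre and aspect terms vanish
  expect_equal(box_ciou(bbox(1, 1, 3, 3), bbox(0, 0, 4, 4)), 0.25)
  a <- c(0, 0, 2, 2); b <- c(1, 1, 3, 3)
  iou <- 1 / 7
  rho2 <- (1 - 2)^2 + (1 - 2)^2
  c2 <- 3^2 + 3^2
  v <- (4 / pi^2) * (atan(1) - atan(1))^2        # equal aspect ratios
  expect_equal(box_ciou(a, b), iou - rho2 / c2 - 0,
               tolerance = 1e-12)
  # unequal aspect ratios engage the consistency term
  a <- c(0, 0, 4, 2); b <- c(0, 0, 2, 4)
  iou2 <- box_iou(a, b)
  rho2b <- (2 - 1)^2 + (1 - 2)^2                  # centre distance
  c2b <- 4^2 + 4^2                                # enclosing-box diagonal
  v2 <- (4 / pi^2) * (atan(2 / 4) - atan(4 / 2))^2
  alpha2 <- v2 / (1 - iou2 + v2 + .Machine$double.eps)
  expect_equal(box_ciou(a, b), iou2 - rho2b / c2b - alpha2 * v2,
               tolerance = 1e-9)
})

test_that("MPDIoU subtracts normalised corner distances from IoU", {
  img <- image_size(10, 10)
  expect_equal(box_mpdiou(bbox(0, 0, 2, 2), bbox(0, 0, 2, 2), img), 1)
  expect_equal(box_mpdiou(c(0, 0, 2, 2), c(1, 1, 3, 3), img),
               1 / 7 - 2 / 200 - 2 / 200)
  expect_equal(mpdiou_loss(c(0, 0, 2, 2), c(1, 1, 3, 3), img),
               1 - (1 / 7 - 0.02))
  expect_equal(mpdiou_loss(c(0, 0, 2, 2), c(0, 0, 2, 2), img), 0)
  set.seed(102)
  for (i in 1:200) {
    a <- random_box(); b <- random_box()
    m <- box_mpdiou(a, b, image_size(640, 480))
    expect_lte(m, box_iou(a, b))
    l <- 1 - m
    expect_gte(l, 0); expect_lte(l, 3)
  }
})

test_that("Inner-IoU scales auxiliary boxes about their centres", {
  a <- c(0, 0, 2, 2); b <- c(1, 1, 3, 3)
  expect_equal(inner_iou(a, b, 1), box_iou(a, b), tolerance = 1e-12)
  expect_equal(inner_iou(bbox(0, 0, 2, 2), bbox(0, 0, 2, 2), 1.15), 1)
  # oracle: rasterise the centre-scaled boxes
  scale_ab <- function(bx, r) {
    cx <- (bx[1] + bx[3]) / 2; cy <- (bx[2] + bx[4]) / 2
    hw <- (bx[3] - bx[1]) * r / 2; hh <- (bx[4] - bx[2]) * r / 2
    c(cx - hw, cy - hh, cx + hw, cy + hh)
  }
  expect_equal(inner_iou(a, b, 1.15),
               raster_iou(scale_ab(a, 1.15), scale_ab(b, 1.15)),
               tolerance = 1e-3)
})

test_that("Inner-MPDIoU loss combines its parts and stays nonnegative", {
  img <- image_size(10, 10)
  expect_equal(inner_mpdiou_loss(c(0, 0, 2, 2), c(0, 0, 2, 2), img, 1.15), 0)
  a <- c(0, 0, 2, 2); b <- c(1, 1, 3, 3)
  expect_equal(inner_mpdiou_loss(a, b, img, 1.15),
               mpdiou_loss(a, b, img) + box_iou(a, b) -
                 inner_iou(a, b, 1.15))
  expect_equal(inner_mpdiou_loss(a, b, img, 1),
               mpdiou_loss(a, b, img), tolerance = 1e-12)
})

test_that("the Gaussian box model is mean = centre, cov = diag(w^2, h^2)/4", {
  g <- gaussian_from_box(bbox(0, 0, 2, 2))
  expect_equal(g$mean, c(1, 1))
  expect_equal(g$cov, diag(c(1, 1)))
  g <- gaussian_from_box(bbox(0, 0, 4, 2))
  expect_equal(g$mean, c(2, 1))
  expect_equal(g$cov, diag(c(4, 1)))
  # round trip: the Gaussian determines the box
  cx <- g$mean[1]; cy <- g$mean[2]
  w <- 2 * sqrt(g$cov[1, 1]); h <- 2 * sqrt(g$cov[2, 2])
  expect_equal(c(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2),
               c(0, 0, 4, 2))
})

test_that("squared Wasserstein distance matches the general Gaussian form", {
  expect_equal(wasserstein2_sq(bbox(0, 0, 2, 2), bbox(0, 0, 2, 2)), 0)
  expect_equal(wasserstein2_sq(bbox(1, 1, 3, 3), bbox(0, 0, 4, 4)), 2)
  set.seed(103)
  for (i in 1:200) {
    a <- random_box(); b <- random_box()
    expect_equal(wasserstein2_sq(a, b), wasserstein2_sq(b, a))
    ga <- gaussian_from_box(a); gb <- gaussian_from_box(b)
    expect_equal(wasserstein2_sq(a, b),
                 gauss_w2sq_ref(ga$mean, ga$cov, gb$mean, gb$cov),
                 tolerance = 1e-9)
  }
})

test_that("NWD is exp(-W2/C), similarity-like, and overlap-free", {
  expect_equal(box_nwd(bbox(0, 0, 2, 2), bbox(0, 0, 2, 2)), 1)
  expect_equal(box_nwd(bbox(1, 1, 3, 3), bbox(0, 0, 4, 4),
                       loss_config(nwd_constant = 12.8)),
               exp(-sqrt(2) / 12.8))
  # disjoint boxes: IoU is blind, NWD is not
  a <- bbox(0, 0, 2, 2); b <- bbox(5, 5, 7, 7)
  expect_equal(box_iou(a, b), 0)
  expect_gt(box_nwd(a, b), 0)
  # strictly decreasing in centre offset at fixed size
  vals <- sapply(seq(0, 5, by = 0.5), function(d)
    box_nwd(c(0, 0, 2, 2), c(d, 0, d + 2, 2)))
  expect_true(all(diff(vals) < 0))
})

test_that("the combined regression loss assembles its terms correctly", {
  img <- image_size(10, 10)
  cfg <- loss_config()
  br <- combined_regression_loss(bbox(0, 0, 2, 2), bbox(0, 0, 2, 2), img, cfg)
  expect_equal(br$L_total, 0)
  a <- bbox(0, 0, 2, 2); b <- bbox(1, 1, 3, 3)
  br <- combined_regression_loss(a, b, img, cfg)
  expect_equal(br$L_nwd, 1 - br$nwd)
  expect_equal(br$L_total,
               cfg$iou_ratio * br$L_inner_mpdiou +
                 (1 - cfg$iou_ratio) * br$L_nwd)
  expect_equal(br$L_inner_mpdiou,
               inner_mpdiou_loss(a, b, img, cfg$inner_ratio))
  expect_equal(br$nwd, box_nwd(a, b, cfg))
  # weighting endpoints
  b1 <- combined_regression_loss(a, b, img, loss_config(iou_ratio = 1))
  expect_equal(b1$L_total, b1$L_inner_mpdiou)
  b0 <- combined_regression_loss(a, b, img, loss_config(iou_ratio = 0))
  expect_equal(b0$L_total, 1 - b0$nwd)
})

test_that("moving the prediction toward the truth monotonically lowers the loss", {
  img <- image_size(640, 480)
  set.seed(104)
  for (rep in 1:5) {
    gtb <- random_box()
    w <- gtb[3] - gtb[1]; h <- gtb[4] - gtb[2]
    start <- c(gtb[1] + 30, gtb[2] - 22, gtb[3] + 30, gtb[4] - 22)
    lam <- seq(0, 1, length.out = 50)
    losses <- sapply(lam, function(l) {
      prd <- (1 - l) * start + l * gtb
      combined_regression_loss(prd, gtb, img)$L_total
    })
    expect_true(all(diff(losses) < 0))
  }
})
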