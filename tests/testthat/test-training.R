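# rule-by-rule reference for the cross-grid anchor assignment
oracle_assign <- function(labels, anchors, input_size, anchor_t = 4) {
  res <- list(p3 = 0L, p4 = 0L, p5 = 0L)
  per_scale <- list(list(), list(), list())
  for (s in 1:3) {
    stride <- anchors$strides[s]
    S <- input_size / stride
    for (li in seq_len(nrow(labels))) {
      gw <- labels$w[li] * input_size / stride
      gh <- labels$h[li] * input_size / stride
      for (a in 1:3) {
        aw <- anchors$wh[(s - 1) * 3 + a, ] / stride
        r <- c(gw / aw[1], aw[1] / gw, gh / aw[2], aw[2] / gh)
        if (max(r) >= anchor_t) next
        gx <- labels$cx[li] * S; gy <- labels$cy[li] * S
        cj <- floor(gx); ci <- floor(gy)
        cand <- list(c(ci, cj))
        if (gx - cj < 0.5 && cj > 0) cand <- c(cand, list(c(ci, cj - 1)))
        if (gx - cj >= 0.5 && cj < S - 1) cand <- c(cand, list(c(ci, cj + 1)))
        if (gy - ci < 0.5 && ci > 0) cand <- c(cand, list(c(ci - 1, cj)))
        if (gy - ci >= 0.5 && ci < S - 1) cand <- c(cand, list(c(ci + 1, cj)))
        for (ce in cand)
          per_scale[[s]][[length(per_scale[[s]]) + 1]] <-
            c(a, ce[1], ce[2], li)
      }
    }
  }
  per_scale
}

test_that("a centered label lands in three cells of its matching scale", {
  anch <- anchor_set(matrix(c(8, 8, 9, 9, 10, 10,
                              16, 16, 18, 18, 20, 20,
                              40, 40, 44, 44, 48, 48), ncol = 2, byrow = TRUE))
  lab <- data.frame(class = 0L, cx = 0.57, cy = 0.57,
                    w = 18 / 128, h = 18 / 128)
  asg <- assign_targets(lab, anch, 128L)
  # at stride 16 the label (18px) matches all three anchors; each gets the
  # home cell plus two neighbours
  expect_equal(nrow(asg$p4), 9)
  expect_equal(asg$skipped, 0)
  # a label 100x off any anchor is skipped entirely
  lab2 <- data.frame(class = 0L, cx = 0.5, cy = 0.5, w = 0.0001, h = 0.0001)
  asg2 <- assign_targets(lab2, anch, 128L)
  expect_equal(nrow(asg2$p3) + nrow(asg2$p4) + nrow(asg2$p5), 0)
  expect_equal(asg2$skipped, 1)
  expect_equal(nrow(assign_targets(lab[0, ], anch, 128L)$p3), 0)
})

test_that("assignment matches an independent rule-by-rule oracle", {
  set.seed(33)
  anch <- anchor_set()
  for (rep in 1:5) {
    n <- sample(1:6, 1)
    lab <- data.frame(class = sample(0:2, n, TRUE),
                      cx = runif(n, 0.1, 0.9), cy = runif(n, 0.1, 0.9),
                      w = runif(n, 0.02, 0.6), h = runif(n, 0.02, 0.6))
    asg <- assign_targets(lab, anch, 640L)
    ref <- oracle_assign(lab, anch, 640L)
    for (s in 1:3) {
      got <- asg[[s]][, c("anchor", "gi", "gj")]
      refm <- do.call(rbind, ref[[s]])
      if (is.null(refm)) {
        expect_equal(nrow(got), 0)
      } else {
        refd <- data.frame(anchor = refm[, 1], gi = refm[, 2], gj = refm[, 3])
        o1 <- do.call(order, got); o2 <- do.call(order, refd)
        expect_equal(got[o1, ], refd[o2, ], ignore_attr = TRUE)
      }
    }
  }
})

test_that("loss vanishes on perfect boxes and behaves on empty labels", {
  anch <- anchor_set()
  no <- 7L
  lab <- data.frame(class = 0L, cx = 0.5, cy = 0.5, w = 16 / 64, h = 30 / 64)
  asg <- assign_targets(lab, anch, 64L)
  raw <- list(p3 = array(-20, c(3 * no, 8, 8)),
              p4 = array(-20, c(3 * no, 4, 4)),
              p5 = array(-20, c(3 * no, 2, 2)))
  # build a perfect prediction at every assigned cell of every scale
  logit <- function(p) log(p / (1 - p))
  for (s in 1:3) {
    a <- asg[[s]]
    for (r in seq_len(nrow(a))) {
      aw <- anch$wh[(s - 1) * 3 + a$anchor[r], ] / anch$strides[s]
      t <- numeric(no)
      t[1] <- logit((a$tx[r] + 0.5) / 2)
      t[2] <- logit((a$ty[r] + 0.5) / 2)
      t[3] <- logit(sqrt(a$gw[r] / aw[1]) / 2)
      t[4] <- logit(sqrt(a$gh[r] / aw[2]) / 2)
      t[5] <- 20; t[6] <- 20; t[7] <- -20
      raw[[s]][(a$anchor[r] - 1) * no + 1:no, a$gi[r] + 1, a$gj[r] + 1] <- t
    }
  }
  l <- compute_loss(raw, asg, 2L, anch)
  expect_lt(l$box, 1e-6)
  expect_lt(l$cls, 1e-6)
  expect_gt(l$obj, 0)
  # no labels: box and cls losses are exactly zero, objectness is not
  asg0 <- assign_targets(lab[0, ], anch, 64L)
  raw0 <- list(p3 = array(0, c(3 * no, 8, 8)), p4 = array(0, c(3 * no, 4, 4)),
               p5 = array(0, c(3 * no, 2, 2)))
  l0 <- compute_loss(raw0, asg0, 2L, anch)
  expect_equal(l0$box, 0)
  expect_equal(l0$cls, 0)
  expect_gt(l0$obj, 0)
})

test_that("loss terms match a straight-line numeric oracle", {
  set.seed(44)
  anch <- anchor_set()
  cfg <- train_config()
  no <- 7L
  lab <- data.frame(class = sample(0:1, 3, TRUE), cx = runif(3, 0.2, 0.8),
                    cy = runif(3, 0.2, 0.8), w = runif(3, 0.1, 0.5),
                    h = runif(3, 0.1, 0.5))
  asg <- assign_targets(lab, anch, 64L)
  raw <- list(p3 = array(rnorm(3 * no * 64), c(3 * no, 8, 8)),
              p4 = array(rnorm(3 * no * 16), c(3 * no, 4, 4)),
              p5 = array(rnorm(3 * no * 4), c(3 * no, 2, 2)))
  got <- compute_loss(raw, asg, 2L, anch, cfg)
  # reference box loss: decode each assignment by hand, average 1 - GIoU
  # within each scale and sum the per-scale means
  ref_box <- 0
  for (s in 1:3) {
    a <- asg[[s]]
    if (!nrow(a)) next
    p <- raw[[s]]
    gsum <- 0
    for (r in seq_len(nrow(a))) {
      t <- p[(a$anchor[r] - 1) * no + 1:no, a$gi[r] + 1, a$gj[r] + 1]
      sg <- 1 / (1 + exp(-t))
      aw <- anch$wh[(s - 1) * 3 + a$anchor[r], ] / anch$strides[s]
      gg <- oracle_giou_center(2 * sg[1] - 0.5, 2 * sg[2] - 0.5,
                               (2 * sg[3])^2 * aw[1], (2 * sg[4])^2 * aw[2],
                               a$tx[r], a$ty[r], a$gw[r], a$gh[r])
      gsum <- gsum + (1 - gg$giou)
    }
    ref_box <- ref_box + gsum / nrow(a)
  }
  expect_equal(got$box, ref_box, tolerance = 1e-8)
  expect_gt(got$obj, 0)
  expect_gt(got$cls, 0)
})

test_that("HSV augmentation respects gains, range and determinism", {
  set.seed(55)
  img <- round(array(runif(24 * 24 * 3), c(24, 24, 3)) * 255) / 255
  expect_equal(augment_hsv(img, gains = c(0, 0, 0)), img)
  out <- augment_hsv(img, seed = 9)
  expect_true(all(out >= 0 & out <= 1))
  expect_equal(out * 255, round(out * 255), tolerance = 1e-9)  # 8-bit grid
  expect_identical(augment_hsv(img, seed = 9), out)
})

test_that("geometric augmentation is an involution under forced flips", {
  set.seed(66)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  lab <- data.frame(class = c(0L, 1L), cx = c(0.3, 0.6), cy = c(0.4, 0.7),
                    w = c(0.2, 0.25), h = c(0.2, 0.15))
  idf <- list(flip = FALSE, scale = 1, tx = 0, ty = 0)
  out_id <- augment_geometric(img, lab, .force = idf)
  expect_equal(out_id$image, img)
  expect_equal(out_id$labels, lab, tolerance = 1e-12)
  ff <- list(flip = TRUE, scale = 1, tx = 0, ty = 0)
  once <- augment_geometric(img, lab, .force = ff)
  twice <- augment_geometric(once$image, once$labels, .force = ff)
  expect_equal(twice$labels, lab, tolerance = 1e-12)
  expect_equal(twice$image, img)
})

test_that("augmented labels equal a corner-transform oracle and stay valid", {
  set.seed(67)
  img <- array(runif(40 * 40 * 3), c(40, 40, 3))
  for (rep in 1:5) {
    n <- 4
    lab <- data.frame(class = sample(0:1, n, TRUE), cx = runif(n, 0.2, 0.8),
                      cy = runif(n, 0.2, 0.8), w = runif(n, 0.1, 0.3),
                      h = runif(n, 0.1, 0.3))
    f <- list(flip = runif(1) < 0.5, scale = runif(1, 0.5, 1.5),
              tx = runif(1, -4, 4), ty = runif(1, -4, 4))
    out <- augment_geometric(img, lab, .force = f)
    if (nrow(out$labels)) {
      expect_true(all(out$labels$cx - out$labels$w / 2 >= -1e-9))
      expect_true(all(out$labels$cx + out$labels$w / 2 <= 1 + 1e-9))
      expect_true(all(out$labels$w > 0 & out$labels$h > 0))
    }
    # corner-transform oracle for the first surviving box
    b <- labels_to_boxes(lab, 40, 40)
    if (f$flip) { t <- 40 - b$x2; b$x2 <- 40 - b$x1; b$x1 <- t }
    cor_x <- function(x) (x - 20) * f$scale + 20 + f$tx
    cor_y <- function(y) (y - 20) * f$scale + 20 + f$ty
    ref <- data.frame(x1 = pmin(pmax(cor_x(b$x1), 0), 40),
                      y1 = pmin(pmax(cor_y(b$y1), 0), 40),
                      x2 = pmin(pmax(cor_x(b$x2), 0), 40),
                      y2 = pmin(pmax(cor_y(b$y2), 0), 40))
    keep <- (ref$x2 - ref$x1) * (ref$y2 - ref$y1) >=
      0.1 * (cor_x(b$x2) - cor_x(b$x1)) * (cor_y(b$y2) - cor_y(b$y1))
    got <- labels_to_boxes(out$labels, 40, 40)
    expect_equal(nrow(got), sum(keep))
    if (any(keep)) {
      expect_equal(got$x1, ref$x1[keep], tolerance = 1e-9)
      expect_equal(got$y2, ref$y2[keep], tolerance = 1e-9)
    }
  }
})

test_that("mosaic composes four tiles deterministically and clips labels", {
  set.seed(77)
  solid <- list(image = array(0.25, c(48, 48, 3)),
                labels = data.frame(class = integer(0), cx = numeric(0),
                                    cy = numeric(0), w = numeric(0),
                                    h = numeric(0)))
  mz <- mosaic_augment(rep(list(solid), 4), output_size = 48, seed = 2)
  expect_true(all(mz$image == 0.25))
  expect_error(mosaic_augment(rep(list(solid), 3)), "four")
  lab <- data.frame(class = 0L, cx = 0.5, cy = 0.5, w = 0.4, h = 0.4)
  smp <- list(image = array(runif(48 * 48 * 3), c(48, 48, 3)), labels = lab)
  m1 <- mosaic_augment(rep(list(smp), 4), output_size = 48, seed = 5)
  m2 <- mosaic_augment(rep(list(smp), 4), output_size = 48, seed = 5)
  expect_identical(m1, m2)
  expect_lte(nrow(m1$labels), 4)
  if (nrow(m1$labels)) {
    expect_true(all(m1$labels$cx - m1$labels$w / 2 >= -1e-9))
    expect_true(all(m1$labels$cy + m1$labels$h / 2 <= 1 + 1e-9))
  }
})

test_that("anchor fitting recovers separated clusters and sorts by area", {
  set.seed(88)
  # degenerate: identical sizes collapse every centroid onto that size
  lab_same <- data.frame(w = rep(0.1, 20), h = rep(0.1, 20))
  a_same <- fit_anchors(lab_same, input_size = 100)
  expect_true(all(abs(a_same$wh - 10) < 1e-9))
  # two well-separated clusters: centroids stay within each cluster's hull
  small <- cbind(runif(30, 0.02, 0.05), runif(30, 0.02, 0.05))
  large <- cbind(runif(30, 0.4, 0.5), runif(30, 0.4, 0.5))
  lab2 <- data.frame(w = c(small[, 1], large[, 1]),
                     h = c(small[, 2], large[, 2]))
  a2 <- fit_anchors(lab2, input_size = 100)
  mids <- a2$wh[, 1]
  expect_true(all(mids < 6 | mids > 38))
  areas <- a2$wh[, 1] * a2$wh[, 2]
  expect_true(all(diff(areas) >= -1e-9))
  expect_warning(fit_anchors(lab_same[1:3, ]), "fewer than")
})

test_that("zero-epoch training saves an initial checkpoint without error", {
  td <- tiny_dataset()
  cfg <- train_config(epochs = 0L, input_size = 64L, seed = 4L)
  mcfg <- model_config(num_classes = 2L, width_multiple = 0.125,
                       input_size = 64L)
  fit <- train_detector(td, cfg, mcfg)
  expect_true(file.exists(fit$checkpoint))
  m <- load_checkpoint(fit$checkpoint)
  expect_equal(count_parameters(m), count_parameters(fit$model))
})
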