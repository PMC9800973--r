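mk_gt <- function(cls, x1, y1, x2, y2, image = "0") {
  data.frame(class = cls, x1 = x1, y1 = y1, x2 = x2, y2 = y2, image = image)
}

test_that("matching follows the greedy single-match rule", {
  gt <- mk_gt(c(0, 0), c(0, 20), c(0, 20), c(10, 30), c(10, 30))
  d <- data.frame(class = 0, score = c(0.9, 0.8),
                  x1 = c(0, 20), y1 = c(0, 20), x2 = c(10, 30), y2 = c(10, 30))
  m <- match_detections(d, gt, 0.5)
  expect_true(all(m$tp))
  expect_equal(m$fn, 0)
  # duplicate detections of one ground truth: first TP, second FP
  dup <- data.frame(class = 0, score = c(0.9, 0.8),
                    x1 = c(0, 0.5), y1 = c(0, 0), x2 = c(10, 10.5), y2 = c(10, 10))
  m2 <- match_detections(dup, gt[1, ], 0.5)
  expect_equal(m2$tp, c(TRUE, FALSE))
  expect_equal(m2$fn, 0)
})

test_that("average precision reproduces the hand-traced envelope", {
  # 2 ground truths, score-ordered flags [TP, FP, TP] -> AP = 5/6
  curve <- pr_curve(c(TRUE, FALSE, TRUE), 2)
  expect_equal(average_precision(curve), 5 / 6, tolerance = 1e-12)
  expect_equal(average_precision(pr_curve(c(TRUE, TRUE), 2)), 1)
  expect_equal(average_precision(pr_curve(logical(0), 2)), 0)
  expect_error(pr_curve(TRUE, 0), "ground truth")
})

test_that("AP is a rank statistic and behaves under added TPs/FPs", {
  set.seed(6)
  for (rep in 1:5) {
    tp <- runif(12) < 0.5
    n_gt <- sum(tp) + sample(0:3, 1)
    if (n_gt == 0) n_gt <- 1
    ap <- average_precision(pr_curve(tp, n_gt))
    expect_equal(ap, oracle_ap(tp, n_gt), tolerance = 2e-3)
    # appending a lowest-score FP never increases AP
    ap_fp <- average_precision(pr_curve(c(tp, FALSE), n_gt))
    expect_lte(ap_fp, ap + 1e-12)
    # prepending a top-score TP (with one more gt) never decreases it
    ap_tp <- average_precision(pr_curve(c(TRUE, tp), n_gt + 1))
    expect_gte(ap_tp, ap - 0.34)  # recall base changes; sanity bound
  }
})

test_that("score rescaling leaves the evaluation unchanged", {
  set.seed(17)
  gt <- mk_gt(rep(0, 4), c(0, 20, 40, 60), rep(0, 4), c(10, 30, 50, 70), rep(10, 4))
  d <- data.frame(class = 0, score = c(0.9, 0.7, 0.5, 0.3),
                  x1 = c(0, 20, 40, 61), y1 = 0, x2 = c(10, 30, 50, 71), y2 = 10)
  d$image <- "0"
  r1 <- evaluate_detections(d, gt, 1)
  d2 <- d; d2$score <- d2$score * 0.5
  r2 <- evaluate_detections(d2, gt, 1)
  expect_equal(r1$map50, r2$map50)
  expect_equal(r1$ap, r2$ap)
})

test_that("evaluate aggregates per-threshold APs per the stated identities", {
  gt <- mk_gt(c(0, 1), c(0, 20), c(0, 20), c(10, 30), c(10, 30))
  d <- data.frame(class = c(0, 1), score = c(0.9, 0.8),
                  x1 = c(0, 20), y1 = c(0, 20), x2 = c(10, 30), y2 = c(10, 30),
                  image = "0")
  r <- evaluate_detections(d, gt, 2)
  expect_equal(unname(r$ap), matrix(1, 2, 10))   # perfect IoU-1 detections
  expect_equal(r$map50, 1)
  expect_equal(r$map5095, 1)
  # mAP@[0.5:0.95] equals the mean over thresholds of per-threshold mAPs
  expect_equal(r$map5095, mean(colMeans(r$ap)))
  # absent classes are excluded from means, with a log note
  expect_message(r3 <- evaluate_detections(d, gt, 3), "absent")
  expect_equal(r3$skipped_classes, 2)
  expect_equal(r3$map50, 1)
})

test_that("evaluation agrees with an independent reference on random scenes", {
  set.seed(20)
  for (rep in 1:20) {
    n_gt <- sample(2:6, 1)
    gx <- runif(n_gt, 0, 80); gy <- runif(n_gt, 0, 80)
    gt <- mk_gt(sample(0:1, n_gt, TRUE), gx, gy, gx + runif(n_gt, 5, 15),
                gy + runif(n_gt, 5, 15))
    n_d <- sample(3:9, 1)
    pick <- sample(n_gt, n_d, replace = TRUE)
    jit <- matrix(rnorm(n_d * 4, 0, 3), n_d)
    d <- data.frame(class = gt$class[pick], score = runif(n_d),
                    x1 = gt$x1[pick] + jit[, 1], y1 = gt$y1[pick] + jit[, 2],
                    x2 = gt$x2[pick] + jit[, 3], y2 = gt$y2[pick] + jit[, 4],
                    image = "0")
    d <- d[d$x2 > d$x1 & d$y2 > d$y1, , drop = FALSE]
    if (!nrow(d)) next
    r <- suppressMessages(evaluate_detections(d, gt, 2))
    # reference: independent matcher trace + fine-grid AP, per class/threshold
    for (cl in unique(gt$class)) {
      m <- match_detections(d[d$class == cl, , drop = FALSE],
                            gt[gt$class == cl, , drop = FALSE], 0.5)
      ref <- oracle_ap(m$tp, sum(gt$class == cl))
      expect_equal(r$ap[cl + 1, 1], ref, tolerance = 1e-3)
    }
  }
})

test_that("salt-and-pepper noise corrupts exactly the requested pixel count", {
  img <- array(0.5, c(40, 50, 3))
  expect_equal(add_salt_pepper(img, 0), img)
  out <- add_salt_pepper(img, 0.1, seed = 3)
  changed <- which(out[, , 1] != 0.5)
  expect_equal(length(changed), round(0.1 * 40 * 50))
  expect_true(all(out[, , 1][changed] %in% c(0, 1)))
  # all three channels get the same mask and value
  expect_equal(out[, , 1], out[, , 2])
  expect_equal(add_salt_pepper(img, 0.1, seed = 3), out)   # reproducible
})

test_that("gaussian noise has the configured mean and clips to [0,1]", {
  img <- array(0.4, c(80, 80, 3))
  out <- add_gaussian_noise(img, mean = 0.1, std = 0.05, seed = 5)
  expect_true(all(out >= 0 & out <= 1))
  added <- mean(out - img)
  expect_lt(abs(added - 0.1), 3 * 0.05 / sqrt(length(img)) + 1e-3)
  expect_equal(add_gaussian_noise(img, seed = 5), out)
  # zero std is a uniform brightening
  expect_equal(add_gaussian_noise(img, mean = 0.1, std = 0), img + 0.1)
  expect_error(add_gaussian_noise(img, std = -1), "std")
})
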