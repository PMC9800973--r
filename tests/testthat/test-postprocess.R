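mk_dets <- function(cls, score, x1, y1, x2, y2) {
  data.frame(class = cls, score = score, x1 = x1, y1 = y1, x2 = x2, y2 = y2)
}

test_that("IoU and GIoU reproduce hand geometry", {
  a <- c(0, 0, 2, 2)
  expect_equal(box_iou(a, a), 1)
  expect_equal(box_iou(a, c(5, 5, 6, 6)), 0)
  expect_equal(box_iou(a, c(0, 0, 2, 1)), 0.5)
  expect_warning(v <- box_iou(a, c(1, 1, 1, 3)), "degenerate")
  expect_equal(v, 0)

  expect_equal(box_giou(a, a), 1)
  expect_equal(box_giou(c(0, 0, 1, 1), c(1, 0, 2, 1)), 0)
  # receding boxes approach the GIoU limit of -1
  far <- box_giou(c(0, 0, 1, 1), c(1e6, 0, 1e6 + 1, 1))
  expect_lt(far, -0.99)
  expect_gte(far, -1)
})

test_that("classical NMS keeps disjoint boxes and suppresses duplicates", {
  d <- mk_dets(c(0, 0), c(0.9, 0.8), c(0, 10), c(0, 10), c(2, 12), c(2, 12))
  expect_equal(nrow(nms(d, 0.45)), 2)
  dup <- mk_dets(c(0, 0), c(0.8, 0.9), c(0, 0), c(0, 0), c(2, 2), c(2, 2))
  kept <- nms(dup, 0.45)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$score, 0.9)
  # the IoU-0.5 pair with threshold 0.45: lower-score box removed
  pair <- mk_dets(c(0, 0), c(0.9, 0.8), c(0, 0), c(0, 0), c(2, 2), c(2, 1))
  expect_equal(nrow(nms(pair, 0.45)), 1)
  expect_error(nms(pair, 1.5), "iou_thr")
})

test_that("soft-NMS applies the Gaussian rescale exactly", {
  pair <- mk_dets(c(0, 0), c(0.9, 0.8), c(0, 0), c(0, 0), c(2, 2), c(2, 1))
  out <- soft_nms(pair, alpha = 0.5, final_thr = 0)
  expect_equal(nrow(out), 2)
  expect_equal(sort(out$score), sort(c(0.9, 0.8 * exp(-2))), tolerance = 1e-12)
  # disjoint boxes keep their scores (penalty exp(0) = 1)
  d <- mk_dets(c(0, 0), c(0.9, 0.8), c(0, 10), c(0, 10), c(2, 12), c(2, 12))
  expect_equal(sort(soft_nms(d, final_thr = 0)$score), c(0.8, 0.9))
  expect_error(soft_nms(pair, alpha = 0), "alpha")
})

test_that("soft-NMS agrees with the brute-force greedy reference", {
  set.seed(99)
  for (rep in 1:3) {
    n <- 50
    cx <- runif(n, 0, 90); cy <- runif(n, 0, 90)
    w <- runif(n, 4, 20); h <- runif(n, 4, 20)
    d <- mk_dets(sample(0:2, n, TRUE), runif(n),
                 cx, cy, cx + w, cy + h)
    got <- soft_nms(d, alpha = 0.5, final_thr = 0.001)
    ref <- oracle_soft_nms(d, alpha = 0.5, final_thr = 0.001)
    expect_equal(got$score, ref$score, tolerance = 1e-12)
    expect_equal(got[, c("x1", "y1", "x2", "y2")], ref[, c("x1", "y1", "x2", "y2")],
                 ignore_attr = TRUE)
  }
})

test_that("soft-NMS invariants: contraction, count preservation, class isolation", {
  set.seed(123)
  n <- 30
  cx <- runif(n, 0, 50); cy <- runif(n, 0, 50)
  d <- mk_dets(sample(0:1, n, TRUE), runif(n), cx, cy,
               cx + runif(n, 5, 15), cy + runif(n, 5, 15))
  out <- soft_nms(d, final_thr = 0)
  expect_equal(nrow(out), n)                     # final_thr 0 drops nothing
  m <- merge(d, out, by = c("x1", "y1", "x2", "y2"))
  expect_true(all(m$score.y <= m$score.x + 1e-12))  # never increases a score
  # class isolation: adding boxes of another class leaves scores unchanged
  d0 <- d[d$class == 0, , drop = FALSE]
  solo <- soft_nms(d0, final_thr = 0)
  joint <- soft_nms(d, final_thr = 0)
  joint0 <- joint[joint$class == 0, , drop = FALSE]
  expect_equal(sort(solo$score), sort(joint0$score), tolerance = 1e-12)
})

test_that("soft-NMS monotonicity and the small-alpha hard-NMS limit", {
  # pairwise: for a fixed highest-score box, a larger IoU neighbour is
  # rescored lower (two boxes at a time, so no cascading penalties)
  shifts <- c(1, 3, 5, 8)
  resc <- vapply(shifts, function(s) {
    d <- mk_dets(c(0, 0), c(0.9, 0.8), c(0, s), c(0, 0),
                 c(10, 10 + s), c(10, 10))
    min(soft_nms(d, alpha = 0.5, final_thr = 0)$score)
  }, numeric(1))
  expect_true(all(diff(resc) > 0))               # larger IoU => smaller score
  # alpha -> 0: overlapping boxes vanish, disjoint survive
  d2 <- mk_dets(c(0, 0, 0), c(0.9, 0.8, 0.7),
                c(0, 1, 40), c(0, 0, 0), c(10, 11, 50), c(10, 10, 10))
  tiny <- soft_nms(d2, alpha = 1e-4, final_thr = 1e-3)
  expect_equal(nrow(tiny), 2)
  expect_equal(sort(tiny$score), c(0.7, 0.9))
})

test_that("detections round-trip through delimited text", {
  d <- mk_dets(c(0, 2), c(0.5, 0.25), c(0, 5), c(1, 6), c(2, 9), c(3, 10))
  d$image <- c("img1", "img2")
  p <- tempfile(fileext = ".tsv")
  write_detections(d, p)
  back <- read_detections(p)
  expect_equal(back$score, d$score)
  expect_equal(back$x1, d$x1)
  expect_equal(back$image, d$image)
})
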