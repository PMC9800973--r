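tiny_cfg <- function(...) {
  model_config(num_classes = 2L, width_multiple = 0.125,
               depth_multiple = 0.33, input_size = 64L, ...)
}

test_that("forward shapes follow the stride arithmetic and toggles keep them", {
  set.seed(1)
  m <- build_model(tiny_cfg(use_cla = FALSE, use_gsppf = FALSE))
  raw <- model_forward(m, array(0.5, c(64, 64, 3)))
  expect_equal(dim(raw$p3), c(3L * 7L, 8L, 8L))
  expect_equal(dim(raw$p4), c(3L * 7L, 4L, 4L))
  expect_equal(dim(raw$p5), c(3L * 7L, 2L, 2L))
  set.seed(1)
  m2 <- build_model(tiny_cfg(use_cla = TRUE, use_gsppf = TRUE))
  raw2 <- model_forward(m2, array(0.5, c(64, 64, 3)))
  expect_equal(lapply(raw2, dim), lapply(raw, dim))
  expect_true(all(vapply(raw2, function(r) all(is.finite(r)), logical(1))))
  expect_error(model_config(input_size = 100), "divisible by 32")
})

test_that("two forward passes with identical weights are bitwise identical", {
  set.seed(2)
  m <- build_model(tiny_cfg())
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  r1 <- model_forward(m, img)
  r2 <- model_forward(m, img)
  expect_identical(r1, r2)
})

test_that("attention adds parameters; the pooling swap changes the count", {
  set.seed(3)
  base <- count_parameters(build_model(tiny_cfg(use_cla = FALSE, use_gsppf = FALSE)))
  cla <- count_parameters(build_model(tiny_cfg(use_cla = TRUE, use_gsppf = FALSE)))
  gsp <- count_parameters(build_model(tiny_cfg(use_cla = FALSE, use_gsppf = TRUE)))
  full <- count_parameters(build_model(tiny_cfg(use_cla = TRUE, use_gsppf = TRUE)))
  expect_gt(cla, base)
  expect_gt(full, gsp)
  # the grouped cascade re-budgets rather than inflates the pooling stage
  expect_false(gsp == base)
})

test_that("parameter and FLOP counts match closed forms on a single conv", {
  reg <- pestyolo:::new_param_registry()
  cv <- pestyolo:::plain_conv(reg, "c", 3L, 16L, k = 3L, pad = 1L)
  n <- sum(vapply(reg$params, function(p) length(p$value), numeric(1)))
  expect_equal(n, 3 * 16 * 9 + 16)      # 448
  ag_stop_tape(); ag_reset_macs()
  out <- cv$forward(ag_leaf(array(0, c(3, 8, 8))))
  expect_equal(2 * ag_get_macs(), 2 * 3 * 16 * 9 * 8 * 8)
})

test_that("decode reproduces the zero-logit fixed point and the loop oracle", {
  anch <- anchor_set()
  S <- 8L; no <- 7L
  raw0 <- list(p3 = array(0, c(3 * no, S, S)),
               p4 = array(0, c(3 * no, S / 2, S / 2)),
               p5 = array(0, c(3 * no, S / 4, S / 4)))
  d <- decode_predictions(raw0, anch, conf_thr = 0.2, input_size = 64L)
  # zero logits: every box sits at its cell center with the anchor size,
  # score 0.25
  expect_true(all(abs(d$score - 0.25) < 1e-12))
  expect_equal(nrow(d), 3 * (S^2 + (S / 2)^2 + (S / 4)^2))
  # threshold 1.0 yields nothing (scores are products of sigmoids < 1)
  expect_equal(nrow(decode_predictions(raw0, anch, 1.0, 64L)), 0)

  set.seed(11)
  raw <- list(p3 = array(rnorm(3 * no * S * S), c(3 * no, S, S)),
              p4 = array(rnorm(3 * no * 16), c(3 * no, 4, 4)),
              p5 = array(rnorm(3 * no * 4), c(3 * no, 2, 2)))
  got <- decode_predictions(raw, anch, conf_thr = 0.1, input_size = 64L)
  ref <- rbind(oracle_decode(raw$p3, anch$wh[1:3, ], 8, 0.1, 64),
               oracle_decode(raw$p4, anch$wh[4:6, ], 16, 0.1, 64),
               oracle_decode(raw$p5, anch$wh[7:9, ], 32, 0.1, 64))
  ref <- ref[order(-ref$score), ]
  expect_equal(nrow(got), nrow(ref))
  expect_equal(got$score, ref$score, tolerance = 1e-10)
  expect_equal(got$x1, ref$x1, tolerance = 1e-9)
  expect_equal(got$class, ref$class)
})

test_that("the stem is translation-covariant: a one-stride shift moves the map", {
  set.seed(9)
  reg <- pestyolo:::new_param_registry()
  stem <- pestyolo:::conv_block(reg, "s", 3L, 8L, 6L, 2L, pad = 2L)
  img <- array(runif(3 * 40 * 40), c(3, 40, 40))
  shifted <- img
  shifted[, , 3:40] <- img[, , 1:38]   # shift right by one stride (2 px)
  ag_stop_tape()
  y1 <- stem$forward(ag_leaf(img))$value
  y2 <- stem$forward(ag_leaf(shifted))$value
  # interior columns of the shifted response equal the original, moved by
  # one cell (boundary columns differ by construction)
  expect_equal(y2[, 3:18, 4:19], y1[, 3:18, 3:18], tolerance = 1e-4)
})

test_that("checkpoints round-trip weights and running statistics", {
  set.seed(5)
  m <- build_model(tiny_cfg())
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  # perturb running stats via one training-mode pass
  ag_stop_tape()
  invisible(m$forward(ag_leaf(pestyolo:::as_chw(img)), training = TRUE))
  p <- tempfile(fileext = ".rds")
  save_checkpoint(m, p)
  m2 <- load_checkpoint(p)
  expect_identical(model_forward(m2, img), model_forward(m, img))
})

test_that("the architecture summary tabulates stages with shapes and params", {
  set.seed(6)
  m <- build_model(tiny_cfg())
  s <- architecture_summary(m)
  expect_true(all(c("layer", "output_shape", "params") %in% names(s)))
  expect_true("gsppf" %in% s$layer)
  expect_gt(sum(s$params), 0.9 * count_parameters(m))
})
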