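# Single-threaded BLAS keeps floating-point reductions, and therefore the
# seeded training trajectories, reproducible across runs.
Sys.setenv(OPENBLAS_NUM_THREADS = "1", OMP_NUM_THREADS = "1")

# Independent straight-line / nested-loop reference implementations used to
# check the vectorized package code. These deliberately avoid the package's
# computational kernels (im2col convolutions, the autodiff graph) and work
# element by element from the defining formulas.

rnd_map <- function(C, H, W) array(rnorm(C * H * W), c(C, H, W))

leaky_ref <- function(x, slope) ifelse(x >= 0, x, slope * x)
sigmoid_ref <- function(x) 1 / (1 + exp(-x))
silu_ref <- function(x) x * sigmoid_ref(x)

# CLA reference: Eqs-style nested-loop evaluation of directional pooling,
# shared bottleneck (+ eval-mode BN, eps 1e-5), directional expansion
# gates, local context and the final four-factor product.
oracle_cla <- function(x, p, local = TRUE) {
  d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]
  cr <- nrow(p$w_shared)
  z_h <- matrix(0, C, H); z_w <- matrix(0, C, W)
  for (c in 1:C) {
    for (h in 1:H) z_h[c, h] <- mean(x[c, h, ])
    for (w in 1:W) z_w[c, w] <- mean(x[c, , w])
  }
  zz <- cbind(z_h, z_w)                    # C x (H+W)
  f <- matrix(0, cr, H + W)
  for (q in 1:cr) for (t in 1:(H + W)) {
    v <- sum(p$w_shared[q, ] * zz[, t])
    v <- (v - p$bn_mean[q]) / sqrt(p$bn_var[q] + 1e-5) * p$bn_gamma[q] + p$bn_beta[q]
    f[q, t] <- leaky_ref(v, p$negative_slope)
  }
  g_h <- matrix(0, C, H); g_w <- matrix(0, C, W)
  for (c in 1:C) {
    for (h in 1:H) g_h[c, h] <- sigmoid_ref(sum(p$w_h[c, ] * f[, h]) + p$b_h[c])
    for (w in 1:W) g_w[c, w] <- sigmoid_ref(sum(p$w_w[c, ] * f[, H + w]) + p$b_w[c])
  }
  out <- array(0, d)
  for (c in 1:C) for (i in 1:H) for (j in 1:W) {
    v <- x[c, i, j] * g_h[c, i] * g_w[c, j]
    if (local) {
      hid <- leaky_ref(as.vector(p$w_c1 %*% x[, i, j]) + p$b_c1,
                       p$negative_slope)
      xl <- leaky_ref(as.vector(p$w_c2 %*% hid) + p$b_c2, p$negative_slope)[c]
      v <- v * xl
    }
    out[c, i, j] <- v
  }
  list(out = out, g_h = g_h, g_w = g_w, z_h = z_h, z_w = z_w)
}

# nested-loop same-size max pool, odd kernel, stride 1
oracle_maxpool <- function(x, k) {
  d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]
  p <- (k - 1) / 2
  out <- array(0, d)
  for (c in 1:C) for (i in 1:H) for (j in 1:W) {
    ri <- max(1, i - p):min(H, i + p)
    cj <- max(1, j - p):min(W, j + p)
    out[c, i, j] <- max(x[c, ri, cj])
  }
  out
}

# "Convs" reference: 1x1 conv + eval BN + SiLU, elementwise
oracle_convs <- function(x, cw) {
  d <- dim(x); H <- d[2]; W <- d[3]
  co <- nrow(cw$w)
  out <- array(0, c(co, H, W))
  for (i in 1:H) for (j in 1:W) {
    v <- as.vector(cw$w %*% x[, i, j])
    v <- (v - cw$bn_mean) / sqrt(cw$bn_var + 1e-5) * cw$bn_g + cw$bn_b
    out[, i, j] <- silu_ref(v)
  }
  out
}

oracle_sppf <- function(x, cfg) {
  y0 <- oracle_convs(x, cfg$sppf_cv1)
  y1 <- oracle_maxpool(y0, cfg$kernel)
  y2 <- oracle_maxpool(y1, cfg$kernel)
  y3 <- oracle_maxpool(y2, cfg$kernel)
  cc <- array(0, c(4L * dim(y0)[1], dim(y0)[2], dim(y0)[3]))
  n <- dim(y0)[1]
  cc[1:n, , ] <- y0; cc[n + 1:n, , ] <- y1
  cc[2 * n + 1:n, , ] <- y2; cc[3 * n + 1:n, , ] <- y3
  oracle_convs(cc, cfg$sppf_cv2)
}

oracle_gsppf <- function(v, cfg) {
  x <- oracle_convs(v, cfg$gsppf$entry)
  C <- dim(x)[1]; gc <- C / cfg$group_count
  groups <- lapply(1:cfg$group_count, function(i) x[(i - 1) * gc + 1:gc, , , drop = FALSE])
  inner <- function(z, gw) {
    y0 <- oracle_convs(z, gw$cv1)
    y1 <- oracle_maxpool(y0, cfg$kernel)
    y2 <- oracle_maxpool(y1, cfg$kernel)
    y3 <- oracle_maxpool(y2, cfg$kernel)
    n <- dim(y0)[1]
    cc <- array(0, c(4L * n, dim(y0)[2], dim(y0)[3]))
    cc[1:n, , ] <- y0; cc[n + 1:n, , ] <- y1
    cc[2 * n + 1:n, , ] <- y2; cc[3 * n + 1:n, , ] <- y3
    oracle_convs(cc, gw$cv2)
  }
  ys <- vector("list", cfg$group_count)
  ys[[1]] <- groups[[1]]
  ys[[2]] <- inner(groups[[2]], cfg$gsppf$groups[[1]])
  for (i in 3:cfg$group_count)
    ys[[i]] <- inner(groups[[i]] + ys[[i - 1]], cfg$gsppf$groups[[i - 1]])
  n <- gc
  cc <- array(0, c(C, dim(x)[2], dim(x)[3]))
  for (i in 1:cfg$group_count) cc[(i - 1) * n + 1:n, , ] <- ys[[i]]
  oracle_convs(cc, cfg$gsppf$exit)
}

# brute-force greedy Gaussian soft suppression, one class at a time
oracle_soft_nms <- function(dets, alpha, final_thr) {
  res <- list()
  for (cl in sort(unique(dets$class))) {
    d <- dets[dets$class == cl, , drop = FALSE]
    scores <- d$score
    pending <- seq_len(nrow(d))
    kept <- integer(0)
    while (length(pending)) {
      i <- pending[order(scores[pending], decreasing = TRUE)[1]]
      kept <- c(kept, i)
      pending <- setdiff(pending, i)
      for (j in pending) {
        ov <- box_iou(as.numeric(d[i, c("x1", "y1", "x2", "y2")]),
                      as.numeric(d[j, c("x1", "y1", "x2", "y2")]))
        scores[j] <- scores[j] * exp(-ov / alpha^2)
      }
    }
    d$score <- scores
    res[[length(res) + 1]] <- d[scores >= final_thr, , drop = FALSE]
  }
  out <- do.call(rbind, res)
  out[order(-out$score), , drop = FALSE]
}

# fine-grid reference AP: mean over a dense recall grid of the maximum
# precision at equal-or-higher recall
oracle_ap <- function(tp, n_gt, grid_n = 20000) {
  ctp <- cumsum(tp); cfp <- cumsum(!tp)
  rec <- ctp / n_gt; prec <- ctp / pmax(ctp + cfp, 1)
  rs <- seq(1 / grid_n, 1, length.out = grid_n)
  vals <- vapply(rs, function(r) {
    ok <- rec >= r - 1e-12
    if (any(ok)) max(prec[ok]) else 0
  }, numeric(1))
  mean(vals)
}

# independent per-cell decode of one raw prediction scale
oracle_decode <- function(p, anchors_wh, stride, conf_thr, input_size) {
  no <- dim(p)[1] / 3; nc <- no - 5
  S <- dim(p)[2]
  rows <- list()
  for (a in 1:3) for (gi in 1:S) for (gj in 1:S) {
    t <- p[(a - 1) * no + 1:no, gi, gj]
    sg <- sigmoid_ref(t)
    cx <- (2 * sg[1] - 0.5 + (gj - 1)) * stride
    cy <- (2 * sg[2] - 0.5 + (gi - 1)) * stride
    bw <- (2 * sg[3])^2 * anchors_wh[a, 1]
    bh <- (2 * sg[4])^2 * anchors_wh[a, 2]
    cls <- which.max(sg[5 + 1:nc])
    sc <- sg[5] * sg[5 + cls]
    if (sc < conf_thr) next
    x1 <- min(max(cx - bw / 2, 0), input_size)
    y1 <- min(max(cy - bh / 2, 0), input_size)
    x2 <- min(max(cx + bw / 2, 0), input_size)
    y2 <- min(max(cy + bh / 2, 0), input_size)
    if (x2 <= x1 || y2 <= y1) next   # fully clipped away
    rows[[length(rows) + 1]] <- data.frame(
      class = cls - 1L, score = sc, x1 = x1, y1 = y1, x2 = x2, y2 = y2)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(class = integer(0), score = numeric(0),
                                      x1 = numeric(0), y1 = numeric(0),
                                      x2 = numeric(0), y2 = numeric(0))
  out
}

# independent GIoU on center-form boxes (numeric vectors)
oracle_giou_center <- function(px, py, pw, ph, tx, ty, tw, th) {
  ax1 <- px - pw / 2; ax2 <- px + pw / 2; ay1 <- py - ph / 2; ay2 <- py + ph / 2
  bx1 <- tx - tw / 2; bx2 <- tx + tw / 2; by1 <- ty - th / 2; by2 <- ty + th / 2
  iw <- pmax(0, pmin(ax2, bx2) - pmax(ax1, bx1))
  ih <- pmax(0, pmin(ay2, by2) - pmax(ay1, by1))
  inter <- iw * ih
  union <- pw * ph + tw * th - inter + 1e-9
  iou <- inter / union
  enc <- (pmax(ax2, bx2) - pmin(ax1, bx1)) * (pmax(ay2, by2) - pmin(ay1, by1)) + 1e-9
  list(iou = iou, giou = iou - (enc - union) / enc)
}

# tiny dataset shared by the heavier end-to-end tests, built once
fixture_env <- new.env(parent = emptyenv())

tiny_dataset <- function() {
  if (!is.null(fixture_env$dataset)) return(fixture_env$dataset)
  td <- file.path(tempdir(), "pestyolo_tiny_ds")
  unlink(td, recursive = TRUE)
  spec <- scene_spec(image_size = 64L, n_insects = 3L,
                     size_range = c(0.2, 0.4), outlier_prob = 0,
                     n_classes = 2L, density = 0.2, n_clutter = 1L,
                     n_reflections = 1L)
  generate_dataset(td, 8L, spec, c(train = 1.0), seed = 11L)
  fixture_env$dataset <- td
  td
}

# one small trained model reused by the overfit and robustness checks
overfit_fit <- function() {
  if (!is.null(fixture_env$fit)) return(fixture_env$fit)
  td <- tiny_dataset()
  cfg <- train_config(epochs = 150L, batch_size = 1L, input_size = 64L,
                      mosaic = FALSE, hsv_gains = c(0, 0, 0), flip_p = 0,
                      translate = 0, scale = c(1, 1), seed = 3L)
  mcfg <- model_config(num_classes = 2L, width_multiple = 0.25,
                       depth_multiple = 0.33, input_size = 64L)
  fixture_env$fit <- train_detector(td, cfg, mcfg,
                                    out_dir = file.path(tempdir(), "pestyolo_fit"))
  fixture_env$fit
}
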