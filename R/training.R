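# Training: cross-grid anchor assignment, the composite detection loss
# (GIoU box regression, IoU-valued objectness targets, binary cross-entropy
# classification), the five online augmentations (HSV jitter, horizontal
# flip, translation, scaling, mosaic), IoU-metric anchor fitting, and a
# plain SGD loop with momentum, weight decay and cosine learning-rate decay.

#' Training configuration
#'
#' Defaults follow the standard recipe for this detector family: initial
#' learning rate 0.01, weight decay 0.0005, momentum 0.937, batch size 16,
#' input 640; HSV gains (0.03, 0.7, 0.5), flip probability 0.5, translation
#' 0.1, scale range (0.5, 1.5), mosaic on.
#'
#' @param lr0 initial learning rate
#' @param lrf final learning rate as a fraction of `lr0` (cosine decay)
#' @param warmup_epochs linear learning-rate ramp at the start of training
#' @param loss_gain fixed multiplier on the per-image loss before
#'   backpropagation (the lineage convention scales the loss by the nominal
#'   batch size, 16, independent of gradient accumulation; the stated lr
#'   regime presumes gradients of this magnitude)
#' @param weight_decay L2 penalty on convolution weights
#' @param momentum SGD momentum
#' @param batch_size images per optimizer step (gradient accumulation)
#' @param epochs training epochs
#' @param input_size square network input
#' @param hsv_gains hue/saturation/value jitter coefficients
#' @param flip_p horizontal flip probability
#' @param translate translation fraction
#' @param scale scaling-factor range
#' @param mosaic enable four-image mosaic composition
#' @param box_w,obj_w,cls_w loss balance weights
#' @param obj_balance per-scale objectness weights (strides 8/16/32)
#' @param anchor_t anchor/label size-ratio matching threshold
#' @param min_area_frac smallest surviving box area fraction after
#'   geometric augmentation
#' @param fit_anchors refit anchor priors to the training labels
#' @param seed master seed for init, shuffling and augmentation draws
#' @return object of class `train_config`
#' @export
train_config <- function(lr0 = 0.01, lrf = 0.01, warmup_epochs = 3L,
                         loss_gain = 16, weight_decay = 0.0005,
                         momentum = 0.937, batch_size = 16L, epochs = 300L,
                         input_size = 640L, hsv_gains = c(0.03, 0.7, 0.5),
                         flip_p = 0.5, translate = 0.1, scale = c(0.5, 1.5),
                         mosaic = TRUE, box_w = 0.05, obj_w = 1.0,
                         cls_w = 0.5, obj_balance = c(4.0, 1.0, 0.4),
                         anchor_t = 4.0, min_area_frac = 0.1,
                         fit_anchors = TRUE, seed = 1L) {
  stopifnot(lr0 > 0, weight_decay >= 0, momentum >= 0, batch_size >= 1,
            epochs >= 0, flip_p >= 0, flip_p <= 1, translate >= 0,
            length(scale) == 2L, scale[1] > 0)
  structure(as.list(environment()), class = "train_config")
}

# ---- target assignment -----------------------------------------------------

#' Assign ground-truth labels to anchors and grid cells
#'
#' Each label is matched to every anchor of a scale whose width and height
#' ratios to the label lie within `anchor_t` (max of ratio and inverse
#' ratio), and to its own grid cell plus the two nearest neighbour cells
#' (cross-grid assignment). Labels matching no anchor at any scale are
#' counted in `skipped`.
#'
#' @param labels data.frame (class, cx, cy, w, h), normalized
#' @param anchors an [anchor_set()]
#' @param input_size network input in pixels
#' @param anchor_t size-ratio threshold
#' @return list with per-scale assignment data.frames (anchor, gi, gj, tx,
#'   ty, gw, gh, cls) and `skipped`
#' @export
assign_targets <- function(labels, anchors, input_size = 640L, anchor_t = 4.0) {
  stopifnot(inherits(anchors, "anchor_set"))
  out <- vector("list", 3L)
  matched_any <- rep(FALSE, nrow(labels))
  for (s in 1:3) {
    stride <- anchors$strides[s]
    S <- input_size %/% stride
    aw <- anchors$wh[(s - 1L) * 3L + 1:3, , drop = FALSE] / stride
    rows <- list()
    for (li in seq_len(nrow(labels))) {
      gw <- labels$w[li] * input_size / stride
      gh <- labels$h[li] * input_size / stride
      rw <- gw / aw[, 1]; rh <- gh / aw[, 2]
      fit <- pmax(pmax(rw, 1 / rw), pmax(rh, 1 / rh)) < anchor_t
      if (!any(fit)) next
      matched_any[li] <- TRUE
      gx <- labels$cx[li] * S; gy <- labels$cy[li] * S
      gj <- floor(gx); gi <- floor(gy)
      cells <- list(c(gi, gj))
      fx <- gx - gj; fy <- gy - gi
      if (fx < 0.5 && gj > 0) cells <- c(cells, list(c(gi, gj - 1)))
      if (fx >= 0.5 && gj < S - 1) cells <- c(cells, list(c(gi, gj + 1)))
      if (fy < 0.5 && gi > 0) cells <- c(cells, list(c(gi - 1, gj)))
      if (fy >= 0.5 && gi < S - 1) cells <- c(cells, list(c(gi + 1, gj)))
      for (a in which(fit)) for (ce in cells) {
        tx <- gx - ce[2]; ty <- gy - ce[1]
        if (tx <= -0.5 || tx >= 1.5 || ty <= -0.5 || ty >= 1.5) next
        rows[[length(rows) + 1L]] <- c(a, ce[1], ce[2], tx, ty, gw, gh,
                                       labels$class[li])
      }
    }
    out[[s]] <- if (length(rows)) {
      m <- do.call(rbind, rows)
      data.frame(anchor = m[, 1], gi = m[, 2], gj = m[, 3], tx = m[, 4],
                 ty = m[, 5], gw = m[, 6], gh = m[, 7], cls = as.integer(m[, 8]))
    } else data.frame(anchor = integer(0), gi = integer(0), gj = integer(0),
                      tx = numeric(0), ty = numeric(0), gw = numeric(0),
                      gh = numeric(0), cls = integer(0))
  }
  names(out) <- c("p3", "p4", "p5")
  out$skipped <- sum(!matched_any)
  out
}

# ---- loss ------------------------------------------------------------------

# graph-mode loss over raw prediction nodes; returns scalar nodes
loss_graph <- function(raw_nodes, asg, nc, anchors, cfg) {
  no <- 5L + nc
  zero <- function() ag_leaf(array(0, 1L))
  box_terms <- list(); cls_terms <- list()
  obj_total <- NULL
  n_box <- 0L
  for (s in 1:3) {
    p <- raw_nodes[[s]]
    d <- dim(p$value); S <- d[2]
    a <- asg[[s]]
    obj_t <- array(0, c(3L, S, S))
    if (nrow(a)) {
      base <- (a$anchor - 1L) * no + 3L * no * a$gi + 3L * no * S * a$gj
      idx <- outer(base, seq_len(no), "+")
      g <- ag_gather(p, idx)                      # n x no
      pxy_x <- ag_scale(ag_sigmoid(ag_cols(g, 1L)), 2, -0.5)
      pxy_y <- ag_scale(ag_sigmoid(ag_cols(g, 2L)), 2, -0.5)
      aw <- anchors$wh[(s - 1L) * 3L + a$anchor, 1L] / anchors$strides[s]
      ah <- anchors$wh[(s - 1L) * 3L + a$anchor, 2L] / anchors$strides[s]
      pw <- ag_mul(ag_square(ag_scale(ag_sigmoid(ag_cols(g, 3L)), 2)),
                   ag_leaf(matrix(aw, ncol = 1)))
      ph <- ag_mul(ag_square(ag_scale(ag_sigmoid(ag_cols(g, 4L)), 2)),
                   ag_leaf(matrix(ah, ncol = 1)))
      giou <- giou_graph(pxy_x, pxy_y, pw, ph,
                         matrix(a$tx, ncol = 1), matrix(a$ty, ncol = 1),
                         matrix(a$gw, ncol = 1), matrix(a$gh, ncol = 1))
      box_terms[[s]] <- ag_scale(ag_sum(ag_scale(giou$giou, -1, 1)), 1 / nrow(a))
      n_box <- n_box + nrow(a)
      # objectness target: detached IoU of the decoded box with its target
      iou_det <- pmin(pmax(giou$iou$value, 0), 1)
      tgt_idx <- cbind(a$anchor, a$gi + 1L, a$gj + 1L)
      for (r in seq_len(nrow(a))) {
        obj_t[tgt_idx[r, 1], tgt_idx[r, 2], tgt_idx[r, 3]] <-
          max(obj_t[tgt_idx[r, 1], tgt_idx[r, 2], tgt_idx[r, 3]], iou_det[r])
      }
      if (nc > 1L) {
        onehot <- matrix(0, nrow(a), nc)
        onehot[cbind(seq_len(nrow(a)), a$cls + 1L)] <- 1
        cls_terms[[s]] <- ag_bce_logits(ag_cols(g, 5L + seq_len(nc)), onehot)
      }
    }
    obj_idx <- array(0L, c(3L, S, S))
    for (an in 1:3) obj_idx[an, , ] <- (an - 1L) * no + 5L +
      3L * no * matrix(0:(S - 1L), S, S) + 3L * no * S *
      matrix(0:(S - 1L), S, S, byrow = TRUE)
    obj_pred <- ag_gather(p, obj_idx)
    obj_l <- ag_scale(ag_bce_logits(obj_pred, obj_t), cfg$obj_balance[s])
    obj_total <- if (is.null(obj_total)) obj_l else ag_add(obj_total, obj_l)
    if (!all(is.finite(obj_l$value)))
      stop("non-finite objectness loss at scale ", c("p3", "p4", "p5")[s])
  }
  # per-scale means are summed across scales (lineage normalization: the
  # stated lr regime presumes gradients of this magnitude)
  box_l <- if (n_box > 0) {
    acc <- NULL
    for (t in box_terms) if (!is.null(t))
      acc <- if (is.null(acc)) t else ag_add(acc, t)
    acc
  } else zero()
  cls_l <- if (length(cls_terms)) {
    acc <- NULL
    for (t in cls_terms) if (!is.null(t)) {
      acc <- if (is.null(acc)) t else ag_add(acc, t)
    }
    acc
  } else zero()
  obj_l <- obj_total
  total <- ag_add(ag_add(ag_scale(box_l, cfg$box_w), ag_scale(obj_l, cfg$obj_w)),
                  ag_scale(cls_l, cfg$cls_w))
  if (!is.finite(total$value))
    stop("non-finite total loss")
  list(box = box_l, obj = obj_l, cls = cls_l, total = total)
}

# vectorized GIoU between predicted (nodes, center form) and constant targets
giou_graph <- function(px, py, pw, ph, tx, ty, tw, th) {
  eps <- 1e-9
  px1 <- ag_sub(px, ag_scale(pw, 0.5)); px2 <- ag_add(px, ag_scale(pw, 0.5))
  py1 <- ag_sub(py, ag_scale(ph, 0.5)); py2 <- ag_add(py, ag_scale(ph, 0.5))
  tx1 <- tx - tw / 2; tx2 <- tx + tw / 2
  ty1 <- ty - th / 2; ty2 <- ty + th / 2
  iw <- ag_clamp_min(ag_sub(ag_pmin(px2, tx2), ag_pmax(px1, tx1)), 0)
  ih <- ag_clamp_min(ag_sub(ag_pmin(py2, ty2), ag_pmax(py1, ty1)), 0)
  inter <- ag_mul(iw, ih)
  pa <- ag_mul(pw, ph)
  union <- ag_scale(ag_sub(ag_add(pa, ag_leaf(tw * th)), inter), 1, eps)
  iou <- ag_div(inter, union)
  ew <- ag_sub(ag_pmax(px2, tx2), ag_pmin(px1, tx1))
  eh <- ag_sub(ag_pmax(py2, ty2), ag_pmin(py1, ty1))
  enc <- ag_scale(ag_mul(ew, eh), 1, eps)
  giou <- ag_sub(iou, ag_div(ag_sub(enc, union), enc))
  list(iou = iou, giou = giou)
}

#' Detection loss for raw predictions
#'
#' `box` sums, over the three detection scales, the per-scale mean of
#' (1 - GIoU) at assigned cells; `obj` sums the per-scale binary
#' cross-entropy of the objectness logits against IoU-valued targets over
#' all cells, weighted by the per-scale balance; `cls` sums the per-scale
#' mean binary cross-entropy over class logits at assigned cells; `total`
#' is their weighted combination. Scales without assignments contribute
#' zero box/cls loss; objectness is always driven toward zero elsewhere.
#'
#' @param raw list of three raw prediction arrays (from [model_forward()])
#' @param assignments result of [assign_targets()]
#' @param num_classes number of classes
#' @param anchors the [anchor_set()] used for assignment
#' @param cfg a [train_config()] (balance weights)
#' @return list of numeric losses: box, obj, cls, total
#' @export
compute_loss <- function(raw, assignments, num_classes, anchors,
                         cfg = train_config()) {
  ag_stop_tape()
  nodes <- lapply(raw[1:3], function(r) ag_leaf(r))
  l <- loss_graph(nodes, assignments, num_classes, anchors, cfg)
  lapply(l, function(n) as.numeric(n$value))
}

# ---- augmentations ---------------------------------------------------------

hsv_to_rgb <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6)
  f <- h6 - i
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  i <- i %% 6
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  list(r = r, g = g, b = b)
}

#' HSV colour-space augmentation
#'
#' Converts to HSV and multiplies hue, saturation and value by random
#' factors uniform in `[1 - g, 1 + g]` per coefficient (hue wraps around),
#' then converts back. Output is quantized to valid 8-bit RGB.
#'
#' @param img numeric HWC array in \[0,1\]
#' @param gains jitter coefficients for (h, s, v)
#' @param seed optional seed for reproducibility
#' @return augmented image, 8-bit-valued in \[0,1\]
#' @export
augment_hsv <- function(img, gains = c(0.03, 0.7, 0.5), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  r <- stats::runif(3, 1 - gains, 1 + gains)
  if (all(gains == 0)) return(img)
  d <- dim(img)
  m <- rbind(as.vector(img[, , 1]), as.vector(img[, , 2]), as.vector(img[, , 3]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 1)
  rgb <- hsv_to_rgb(hsv[1, ] * r[1], pmin(hsv[2, ] * r[2], 1),
                    pmin(hsv[3, ] * r[3], 1))
  out <- array(c(rgb$r, rgb$g, rgb$b), d)
  round(pmin(pmax(out, 0), 1) * 255) / 255
}

#' Geometric augmentation: flip, translation, scaling
#'
#' Applies (in order) an optional horizontal flip, scaling about the image
#' center by a factor drawn from `scale`, and a translation by a uniform
#' fraction of the image size. Labels are remapped by transforming box
#' corners, clipped to the image, and dropped when the surviving area falls
#' below `min_area_frac` of the transformed box.
#'
#' @param img numeric HWC array
#' @param labels normalized label data.frame
#' @param flip_p flip probability
#' @param translate translation fraction (uniform in +-translate)
#' @param scale scaling-factor range
#' @param min_area_frac survival threshold for clipped boxes
#' @param seed optional seed
#' @param .force optional list(flip=, scale=, tx=, ty=) overriding the
#'   random draws (test hook)
#' @return list(image, labels)
#' @export
augment_geometric <- function(img, labels, flip_p = 0.5, translate = 0.1,
                              scale = c(0.5, 1.5), min_area_frac = 0.1,
                              seed = NULL, .force = NULL) {
  if (!is.null(seed)) set.seed(seed)
  H <- dim(img)[1]; W <- dim(img)[2]
  flip <- if (!is.null(.force$flip)) .force$flip else stats::runif(1) < flip_p
  sc <- if (!is.null(.force$scale)) .force$scale else stats::runif(1, scale[1], scale[2])
  tx <- if (!is.null(.force$tx)) .force$tx else stats::runif(1, -translate, translate) * W
  ty <- if (!is.null(.force$ty)) .force$ty else stats::runif(1, -translate, translate) * H
  # forward map (source -> destination), applied after optional flip
  fwd_x <- function(x) (x - W / 2) * sc + W / 2 + tx
  fwd_y <- function(y) (y - H / 2) * sc + H / 2 + ty
  # sample destination pixels from source (nearest neighbour)
  dx <- seq_len(W); dy <- seq_len(H)
  sx <- round((dx - 0.5 - W / 2 - tx) / sc + W / 2 + 0.5)
  sy <- round((dy - 0.5 - H / 2 - ty) / sc + H / 2 + 0.5)
  if (flip) sx <- W + 1 - sx
  ok_x <- sx >= 1 & sx <= W; ok_y <- sy >= 1 & sy <= H
  out <- array(114 / 255, c(H, W, 3L))
  if (any(ok_x) && any(ok_y)) {
    out[which(ok_y), which(ok_x), ] <-
      img[sy[ok_y], sx[ok_x], , drop = FALSE]
  }
  if (nrow(labels)) {
    b <- labels_to_boxes(labels, W, H)
    if (flip) {
      nx1 <- W - b$x2; nx2 <- W - b$x1
      b$x1 <- nx1; b$x2 <- nx2
    }
    x1 <- fwd_x(b$x1); x2 <- fwd_x(b$x2)
    y1 <- fwd_y(b$y1); y2 <- fwd_y(b$y2)
    full_area <- (x2 - x1) * (y2 - y1)
    cx1 <- pmin(pmax(x1, 0), W); cx2 <- pmin(pmax(x2, 0), W)
    cy1 <- pmin(pmax(y1, 0), H); cy2 <- pmin(pmax(y2, 0), H)
    area <- (cx2 - cx1) * (cy2 - cy1)
    keep <- area > 0 & area >= min_area_frac * full_area
    labels <- boxes_to_labels(
      data.frame(class = b$class[keep], x1 = cx1[keep], y1 = cy1[keep],
                 x2 = cx2[keep], y2 = cy2[keep]), W, H)
  }
  list(image = out, labels = labels)
}

#' Mosaic augmentation
#'
#' Composes four samples into one canvas as a 2x2 layout around a random
#' center; each tile is a random crop of its source image. Labels are
#' remapped to mosaic coordinates, clipped, and dropped when almost
#' entirely cropped away.
#'
#' @param samples list of exactly four `list(image, labels)` samples
#' @param output_size mosaic canvas side
#' @param min_area_frac survival threshold for clipped boxes
#' @param seed optional seed
#' @return list(image, labels)
#' @export
mosaic_augment <- function(samples, output_size = 640L, min_area_frac = 0.1,
                           seed = NULL) {
  if (length(samples) != 4L) stop("mosaic needs exactly four samples")
  if (!is.null(seed)) set.seed(seed)
  S <- output_size
  xc <- round(stats::runif(1, 0.3, 0.7) * S)
  yc <- round(stats::runif(1, 0.3, 0.7) * S)
  canvas <- array(114 / 255, c(S, S, 3L))
  corners <- list(c(1, 1, yc, xc), c(1, xc + 1, yc, S),
                  c(yc + 1, 1, S, xc), c(yc + 1, xc + 1, S, S))
  labs <- list()
  for (i in 1:4) {
    co <- corners[[i]]
    th <- co[3] - co[1] + 1L; tw <- co[4] - co[2] + 1L
    img <- samples[[i]]$image
    ih <- dim(img)[1]; iw <- dim(img)[2]
    if (ih < th || iw < tw) {
      pad <- array(114 / 255, c(max(ih, th), max(iw, tw), 3L))
      pad[seq_len(ih), seq_len(iw), ] <- img
      img <- pad; ih <- dim(img)[1]; iw <- dim(img)[2]
    }
    oy <- if (ih > th) sample.int(ih - th, 1L) else 0L
    ox <- if (iw > tw) sample.int(iw - tw, 1L) else 0L
    canvas[co[1]:co[3], co[2]:co[4], ] <-
      img[oy + seq_len(th), ox + seq_len(tw), , drop = FALSE]
    lab <- samples[[i]]$labels
    if (nrow(lab)) {
      b <- labels_to_boxes(lab, dim(samples[[i]]$image)[2],
                           dim(samples[[i]]$image)[1])
      x1 <- b$x1 - ox + co[2] - 1; x2 <- b$x2 - ox + co[2] - 1
      y1 <- b$y1 - oy + co[1] - 1; y2 <- b$y2 - oy + co[1] - 1
      full <- (x2 - x1) * (y2 - y1)
      cx1 <- pmin(pmax(x1, co[2] - 1), co[4]); cx2 <- pmin(pmax(x2, co[2] - 1), co[4])
      cy1 <- pmin(pmax(y1, co[1] - 1), co[3]); cy2 <- pmin(pmax(y2, co[1] - 1), co[3])
      area <- pmax(cx2 - cx1, 0) * pmax(cy2 - cy1, 0)
      keep <- area > 0 & area >= min_area_frac * full
      if (any(keep)) {
        labs[[length(labs) + 1L]] <- data.frame(
          class = b$class[keep], x1 = cx1[keep], y1 = cy1[keep],
          x2 = cx2[keep], y2 = cy2[keep])
      }
    }
  }
  labels <- if (length(labs)) boxes_to_labels(do.call(rbind, labs), S, S)
            else data.frame(class = integer(0), cx = numeric(0),
                            cy = numeric(0), w = numeric(0), h = numeric(0))
  list(image = canvas, labels = labels)
}

# ---- anchor fitting --------------------------------------------------------

#' Fit anchor priors to a label set by IoU k-means
#'
#' Lloyd iteration over label (width, height) pairs in input-size pixels,
#' with assignment by the highest width/height IoU (boxes anchored at a
#' common corner) and centroid update by the member mean. Falls back to the
#' preset anchors with a warning when fewer than `k` labels are available.
#'
#' @param labels data.frame of normalized labels (w, h columns)
#' @param k number of anchors
#' @param input_size pixel scale of the fitted anchors
#' @param iterations Lloyd iterations
#' @param seed seed for the initial centroid draw
#' @return an [anchor_set()], sorted by area ascending, split 3/3/3
#' @export
fit_anchors <- function(labels, k = 9L, input_size = 640L, iterations = 30L,
                        seed = 1L) {
  wh <- cbind(labels$w, labels$h) * input_size
  wh <- wh[wh[, 1] > 0 & wh[, 2] > 0, , drop = FALSE]
  if (nrow(wh) < k) {
    warning("fewer than ", k, " labels; falling back to preset anchors")
    return(anchor_set())
  }
  set.seed(seed)
  cent <- wh[sample.int(nrow(wh), k), , drop = FALSE]
  wh_iou <- function(wh1, cent) {
    inter <- outer(wh1[, 1], cent[, 1], pmin) * outer(wh1[, 2], cent[, 2], pmin)
    a1 <- wh1[, 1] * wh1[, 2]; a2 <- cent[, 1] * cent[, 2]
    inter / (outer(a1, a2, "+") - inter)
  }
  for (it in seq_len(iterations)) {
    assign <- max.col(wh_iou(wh, cent), ties.method = "first")
    for (j in seq_len(k)) {
      m <- assign == j
      if (any(m)) cent[j, ] <- colMeans(wh[m, , drop = FALSE])
    }
  }
  cent <- cent[order(cent[, 1] * cent[, 2]), , drop = FALSE]
  anchor_set(cent)
}

# ---- SGD training loop -----------------------------------------------------

sgd_step <- function(model, vel, lr, momentum, weight_decay, nbatch) {
  for (nm in names(model$reg$params)) {
    p <- model$reg$params[[nm]]
    if (is.null(p$grad)) next
    g <- p$grad / nbatch
    if (weight_decay > 0 && grepl("\\.w$", nm)) g <- g + weight_decay * p$value
    v <- momentum * (vel[[nm]] %||% 0) + g
    vel[[nm]] <- v
    p$value <- p$value - lr * v
    p$grad <- NULL
  }
  vel
}

zero_grads <- function(model) {
  for (p in model$reg$params) p$grad <- NULL
  invisible(NULL)
}

#' Train the detector on a dataset directory
#'
#' Plain SGD with momentum, weight decay on convolution weights, cosine
#' learning-rate decay and per-batch gradient accumulation. Anchors are
#' refitted to the training labels unless disabled. Per-epoch losses (and
#' validation mAP when a `val` split exists and `eval_val` is on) are
#' logged to a CSV; the checkpoint with the best validation mAP (or the
#' final one) is retained.
#'
#' @param dataset_dir dataset root (images/ + labels/ layout)
#' @param cfg a [train_config()]
#' @param model_cfg a [model_config()]; its input_size is overridden by the
#'   training input size
#' @param out_dir output directory for the metrics log and checkpoint;
#'   tempdir by default
#' @param eval_val evaluate mAP on the `val` split each epoch
#' @param verbose print a line per epoch
#' @return list: `model`, `log` (data.frame), `checkpoint` (path),
#'   `anchors`
#' @export
train_detector <- function(dataset_dir, cfg = train_config(),
                           model_cfg = model_config(), out_dir = tempdir(),
                           eval_val = FALSE, verbose = FALSE) {
  set.seed(cfg$seed)
  samples <- read_dataset_split(dataset_dir, "train")
  if (!length(samples)) stop("empty training split under ", dataset_dir)
  model_cfg$input_size <- as.integer(cfg$input_size)
  if (cfg$fit_anchors) {
    all_lab <- do.call(rbind, lapply(samples, `[[`, "labels"))
    model_cfg$anchors <- fit_anchors(all_lab, input_size = cfg$input_size,
                                     seed = cfg$seed)
  }
  model <- build_model(model_cfg)
  anchors <- model_cfg$anchors
  nc <- model_cfg$num_classes
  has_val <- dir.exists(file.path(dataset_dir, "images", "val"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "metrics.csv")
  ckpt_path <- file.path(out_dir, "checkpoint.rds")
  vel <- list()
  logs <- list()
  best_map <- -Inf
  n <- length(samples)
  if (cfg$epochs == 0L) {
    save_checkpoint(model, ckpt_path)
    log <- data.frame(epoch = integer(0), box_loss = numeric(0),
                      obj_loss = numeric(0), cls_loss = numeric(0),
                      total_loss = numeric(0), map50 = numeric(0),
                      map5095 = numeric(0))
    utils::write.csv(log, log_path, row.names = FALSE)
    return(list(model = model, log = log, checkpoint = ckpt_path,
                anchors = anchors))
  }
  for (epoch in seq_len(cfg$epochs)) {
    lr <- cfg$lr0 * ((1 - cfg$lrf) * 0.5 *
                       (1 + cos(pi * (epoch - 1) / cfg$epochs)) + cfg$lrf)
    if (epoch <= cfg$warmup_epochs) lr <- lr * epoch / (cfg$warmup_epochs + 1)
    ord <- sample.int(n)
    sums <- c(box = 0, obj = 0, cls = 0, total = 0)
    in_batch <- 0L
    for (si in ord) {
      smp <- samples[[si]]
      img <- smp$image; lab <- smp$labels
      if (cfg$mosaic && n >= 4L) {
        others <- sample(setdiff(seq_len(n), si), 3L)
        mz <- mosaic_augment(c(list(smp), samples[others]),
                             output_size = cfg$input_size,
                             min_area_frac = cfg$min_area_frac)
        img <- mz$image; lab <- mz$labels
      }
      if (any(cfg$hsv_gains > 0)) img <- augment_hsv(img, cfg$hsv_gains)
      ag <- augment_geometric(img, lab, cfg$flip_p, cfg$translate, cfg$scale,
                              cfg$min_area_frac)
      img <- ag$image; lab <- ag$labels
      if (dim(img)[1] != cfg$input_size || dim(img)[2] != cfg$input_size)
        img <- letterbox(img, cfg$input_size)$image
      asg <- assign_targets(lab, anchors, cfg$input_size, cfg$anchor_t)
      ag_start_tape()
      raw <- model$forward(ag_leaf(as_chw(img)), training = TRUE)
      l <- loss_graph(raw, asg, nc, anchors, cfg)
      ag_backward(ag_scale(l$total, cfg$loss_gain))
      sums <- sums + c(l$box$value, l$obj$value, l$cls$value, l$total$value)
      in_batch <- in_batch + 1L
      if (in_batch >= cfg$batch_size || si == ord[length(ord)]) {
        vel <- sgd_step(model, vel, lr, cfg$momentum, cfg$weight_decay,
                        in_batch)
        in_batch <- 0L
      }
    }
    row <- data.frame(epoch = epoch, box_loss = sums["box"] / n,
                      obj_loss = sums["obj"] / n, cls_loss = sums["cls"] / n,
                      total_loss = sums["total"] / n, map50 = NA_real_,
                      map5095 = NA_real_)
    if (eval_val && has_val) {
      ev <- evaluate_split(model, dataset_dir, "val")
      row$map50 <- ev$map50; row$map5095 <- ev$map5095
      if (ev$map50 > best_map) {
        best_map <- ev$map50
        save_checkpoint(model, ckpt_path)
      }
    }
    logs[[epoch]] <- row
    if (verbose)
      message(sprintf("epoch %3d lr %.4f box %.4f obj %.4f cls %.4f total %.4f",
                      epoch, lr, row$box_loss, row$obj_loss, row$cls_loss,
                      row$total_loss))
  }
  if (!is.finite(best_map)) save_checkpoint(model, ckpt_path)
  log <- do.call(rbind, logs)
  rownames(log) <- NULL
  utils::write.csv(log, log_path, row.names = FALSE)
  list(model = model, log = log, checkpoint = ckpt_path, anchors = anchors)
}

#' Evaluate a model on one dataset split
#'
#' Runs [detect_image()] on every image of the split and scores the pooled
#' detections with [evaluate_detections()].
#'
#' @param model a [pest_model]
#' @param dataset_dir dataset root
#' @param split split name
#' @param conf_thr decode threshold
#' @return an `eval_report`
#' @export
evaluate_split <- function(model, dataset_dir, split = "val",
                           conf_thr = 0.001) {
  samples <- read_dataset_split(dataset_dir, split)
  dets <- list(); gts <- list()
  for (s in samples) {
    d <- detect_image(model, s$image, conf_thr = conf_thr)
    if (nrow(d)) d$image <- s$id
    dets[[length(dets) + 1L]] <- d
    g <- labels_to_boxes(s$labels, dim(s$image)[2], dim(s$image)[1])
    if (nrow(g)) g$image <- s$id
    gts[[length(gts) + 1L]] <- g
  }
  dd <- do.call(rbind, dets)
  suppressMessages(evaluate_detections(
    if (is.null(dd) || !nrow(dd)) empty_detections() else dd,
    do.call(rbind, gts), model$cfg$num_classes))
}
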