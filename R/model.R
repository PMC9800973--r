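# Assembly of the detector: a CSP backbone with a 6x6-conv stem whose CSP
# blocks optionally carry CLA attention, an SPPF or grouped-cascade (GSPPF)
# pooling stage on the deepest map, an FPN+PAN neck, and an anchored
# three-scale head at strides 8/16/32.

#' Detector configuration
#'
#' @param num_classes number of object classes
#' @param depth_multiple,width_multiple depth/width scaling of the CSP
#'   stages (the small variant uses 0.33 / 0.50)
#' @param input_size square network input in pixels; divisible by 32
#' @param use_cla insert a CLA attention block after every backbone CSP stage
#' @param use_gsppf replace the SPPF stage by the grouped cascade
#' @param anchors an [anchor_set()]; defaults to the lineage presets
#' @param cla_reduction bottleneck reduction of the CLA blocks
#' @return object of class `model_config`
#' @export
model_config <- function(num_classes = 24L, depth_multiple = 0.33,
                         width_multiple = 0.5, input_size = 640L,
                         use_cla = TRUE, use_gsppf = TRUE,
                         anchors = NULL, cla_reduction = 32L) {
  input_size <- as.integer(input_size)
  if (input_size %% 32L != 0L)
    stop("input_size must be divisible by 32 (largest stride), got ", input_size)
  if (num_classes < 1L) stop("num_classes must be >= 1")
  if (is.null(anchors)) anchors <- anchor_set()
  structure(list(
    num_classes = as.integer(num_classes),
    depth_multiple = depth_multiple, width_multiple = width_multiple,
    input_size = input_size, use_cla = isTRUE(use_cla),
    use_gsppf = isTRUE(use_gsppf), anchors = anchors,
    cla_reduction = as.integer(cla_reduction)
  ), class = "model_config")
}

#' Anchor priors grouped by stride
#'
#' Nine (width, height) priors in input-image pixels, three per detection
#' stride in {8, 16, 32}. Defaults are the lineage presets fitted on
#' general-purpose data; [fit_anchors()] refits them to a label set.
#'
#' @param wh 9 x 2 numeric matrix of (width, height) pairs, rows grouped
#'   three per stride, strides ascending
#' @return object of class `anchor_set`
#' @export
anchor_set <- function(wh = NULL) {
  if (is.null(wh)) {
    wh <- matrix(c(10, 13, 16, 30, 33, 23,
                   30, 61, 62, 45, 59, 119,
                   116, 90, 156, 198, 373, 326), ncol = 2, byrow = TRUE)
  }
  wh <- as.matrix(wh)
  if (!all(dim(wh) == c(9L, 2L))) stop("anchor set needs a 9 x 2 matrix")
  if (any(wh <= 0)) stop("anchor dimensions must be positive")
  structure(list(wh = wh, strides = c(8L, 16L, 32L)), class = "anchor_set")
}

#' Build the detector network
#'
#' Constructs the full network for a configuration; weights are drawn from
#' the current RNG stream (seed before calling for reproducibility). The
#' returned model exposes a forward pass producing three raw prediction
#' grids at strides 8/16/32.
#'
#' @param cfg a [model_config()]
#' @return object of class `pest_model`
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  reg <- new_param_registry()
  w <- cfg$width_multiple; d <- cfg$depth_multiple
  ch <- function(c) make_divisible(c * w, 8L)
  dn <- function(n) max(1L, round(n * d))
  c1 <- ch(64); c2 <- ch(128); c3 <- ch(256); c4 <- ch(512); c5 <- ch(1024)
  nc <- cfg$num_classes; no <- 5L + nc

  mk_cla <- function(name, c) {
    if (cfg$use_cla) cla_block(reg, name, c, cfg$cla_reduction) else NULL
  }
  b0 <- conv_block(reg, "b0.stem", 3L, c1, 6L, 2L, pad = 2L)
  b1 <- conv_block(reg, "b1.conv", c1, c2, 3L, 2L)
  b2 <- c3_block(reg, "b2.csp", c2, c2, dn(3)); a2 <- mk_cla("b2.cla", c2)
  b3 <- conv_block(reg, "b3.conv", c2, c3, 3L, 2L)
  b4 <- c3_block(reg, "b4.csp", c3, c3, dn(6)); a4 <- mk_cla("b4.cla", c3)
  b5 <- conv_block(reg, "b5.conv", c3, c4, 3L, 2L)
  b6 <- c3_block(reg, "b6.csp", c4, c4, dn(9)); a6 <- mk_cla("b6.cla", c4)
  b7 <- conv_block(reg, "b7.conv", c4, c5, 3L, 2L)
  b8 <- c3_block(reg, "b8.csp", c5, c5, dn(3)); a8 <- mk_cla("b8.cla", c5)
  b9 <- if (cfg$use_gsppf) gsppf_block(reg, "b9.gsppf", c5, c5, 5L)
        else sppf_block(reg, "b9.sppf", c5, c5, 5L)

  h10 <- conv_block(reg, "h10.conv", c5, c4, 1L)
  h13 <- c3_block(reg, "h13.csp", 2L * c4, c4, dn(3), shortcut = FALSE)
  h14 <- conv_block(reg, "h14.conv", c4, c3, 1L)
  h17 <- c3_block(reg, "h17.csp", 2L * c3, c3, dn(3), shortcut = FALSE)
  h18 <- conv_block(reg, "h18.conv", c3, c3, 3L, 2L)
  h20 <- c3_block(reg, "h20.csp", 2L * c3, c4, dn(3), shortcut = FALSE)
  h21 <- conv_block(reg, "h21.conv", c4, c4, 3L, 2L)
  h23 <- c3_block(reg, "h23.csp", 2L * c4, c5, dn(3), shortcut = FALSE)

  det_bias <- function(stride) {
    b <- rep(0, 3L * no)
    for (a in 0:2) {
      off <- a * no
      b[off + 5L] <- log(8 / (cfg$input_size / stride)^2)
      b[off + 5L + seq_len(nc)] <- log(0.6 / (nc - 0.99))
    }
    b
  }
  d3 <- plain_conv(reg, "det.p3", c3, 3L * no, bias_init = det_bias(8))
  d4 <- plain_conv(reg, "det.p4", c4, 3L * no, bias_init = det_bias(16))
  d5 <- plain_conv(reg, "det.p5", c5, 3L * no, bias_init = det_bias(32))

  trace_env <- new.env(parent = emptyenv())
  fwd <- function(x, training = FALSE, trace = FALSE) {
    # networks here see one image per step, so batch statistics are
    # per-image; inference mirrors that (instance-style normalization)
    old_flag <- .ag$bn_force_batch_stats
    .ag$bn_force_batch_stats <- !training
    on.exit(.ag$bn_force_batch_stats <- old_flag)
    shapes <- if (trace) list() else NULL
    note <- function(name, node) {
      if (trace) shapes[[name]] <<- dim(node$value)
      node
    }
    maybe_cla <- function(blk, node) if (is.null(blk)) node else blk$forward(node, training)
    x0 <- note("stem", b0$forward(x, training))
    x1 <- note("conv1", b1$forward(x0, training))
    x2 <- note("csp1", maybe_cla(a2, b2$forward(x1, training)))
    x3 <- note("conv2", b3$forward(x2, training))
    x4 <- note("csp2", maybe_cla(a4, b4$forward(x3, training)))
    x5 <- note("conv3", b5$forward(x4, training))
    x6 <- note("csp3", maybe_cla(a6, b6$forward(x5, training)))
    x7 <- note("conv4", b7$forward(x6, training))
    x8 <- note("csp4", maybe_cla(a8, b8$forward(x7, training)))
    x9 <- note(if (cfg$use_gsppf) "gsppf" else "sppf", b9$forward(x8, training))
    y10 <- note("neck.reduce1", h10$forward(x9, training))
    y12 <- ag_concat(list(ag_upsample2(y10), x6), 1L)
    y13 <- note("neck.csp1", h13$forward(y12, training))
    y14 <- note("neck.reduce2", h14$forward(y13, training))
    y16 <- ag_concat(list(ag_upsample2(y14), x4), 1L)
    p3f <- note("neck.csp2", h17$forward(y16, training))
    y19 <- ag_concat(list(h18$forward(p3f, training), y14), 1L)
    p4f <- note("neck.csp3", h20$forward(y19, training))
    y22 <- ag_concat(list(h21$forward(p4f, training), y10), 1L)
    p5f <- note("neck.csp4", h23$forward(y22, training))
    out <- list(p3 = note("head.p3", d3$forward(p3f, training)),
                p4 = note("head.p4", d4$forward(p4f, training)),
                p5 = note("head.p5", d5$forward(p5f, training)))
    if (trace) trace_env$shapes <- shapes
    out
  }

  structure(list(cfg = cfg, reg = reg, forward = fwd, trace_env = trace_env,
                 channels = c(p3 = c3, p4 = c4, p5 = c5)),
            class = "pest_model")
}

#' Raw forward pass on an image array
#'
#' @param model a [build_model()] result
#' @param img numeric array, either CHW (3 x S x S) or HWC (S x S x 3) in
#'   \[0,1\]; S must match a multiple of 32
#' @param training use batch statistics and record gradients if a tape is
#'   active
#' @return list of three raw prediction arrays (3*(5+nc) x S/8 x S/8, ...)
#' @export
model_forward <- function(model, img, training = FALSE) {
  x <- as_chw(img)
  out <- model$forward(ag_leaf(x), training = training)
  lapply(out, ag_value)
}

as_chw <- function(img) {
  d <- dim(img)
  if (length(d) != 3L) stop("image must be a rank-3 array")
  if (d[1] == 3L) img else aperm(img, c(3, 1, 2))
}

#' Decode raw prediction grids into detections
#'
#' Per cell and anchor: center `(2*sigmoid(t_xy) - 0.5 + cell) * stride`,
#' size `(2*sigmoid(t_wh))^2 * anchor`, score `sigmoid(obj) * max_class
#' sigmoid(cls)`. Boxes are clipped to the image and filtered at
#' `conf_thr`.
#'
#' @param raw list of per-scale raw arrays from [model_forward()]
#' @param anchors an [anchor_set()]
#' @param conf_thr minimum score to keep
#' @param input_size image size the predictions refer to
#' @return data.frame with columns class, score, x1, y1, x2, y2
#' @export
decode_predictions <- function(raw, anchors, conf_thr = 0.25, input_size = 640L) {
  stopifnot(inherits(anchors, "anchor_set"))
  if (length(raw) != 3L) stop("expected three prediction scales")
  out <- vector("list", 3L)
  for (s in 1:3) {
    p <- raw[[s]]
    stride <- anchors$strides[s]
    S <- dim(p)[2]
    if (dim(p)[3] != S || S * stride != input_size)
      stop("prediction grid ", dim(p)[2], "x", dim(p)[3],
           " does not match stride ", stride, " at input size ", input_size)
    no <- dim(p)[1] %/% 3L
    nc <- no - 5L
    rows <- vector("list", 3L)
    for (a in 1:3) {
      blk <- p[(a - 1L) * no + seq_len(no), , , drop = FALSE]
      sig <- 1 / (1 + exp(-blk))
      gi <- matrix(seq_len(S) - 1L, S, S)         # row index = y cell
      gj <- matrix(seq_len(S) - 1L, S, S, byrow = TRUE)
      cx <- (2 * sig[1, , ] - 0.5 + gj) * stride
      cy <- (2 * sig[2, , ] - 0.5 + gi) * stride
      bw <- (2 * sig[3, , ])^2 * anchors$wh[(s - 1L) * 3L + a, 1L]
      bh <- (2 * sig[4, , ])^2 * anchors$wh[(s - 1L) * 3L + a, 2L]
      cls_sig <- array(sig[5L + seq_len(nc), , , drop = FALSE], c(nc, S * S))
      best <- max.col(t(cls_sig), ties.method = "first")
      best_p <- cls_sig[cbind(best, seq_len(S * S))]
      score <- as.vector(sig[5, , ]) * best_p
      keep <- score >= conf_thr
      if (!any(keep)) next
      x1 <- pmin(pmax(as.vector(cx - bw / 2), 0), input_size)
      y1 <- pmin(pmax(as.vector(cy - bh / 2), 0), input_size)
      x2 <- pmin(pmax(as.vector(cx + bw / 2), 0), input_size)
      y2 <- pmin(pmax(as.vector(cy + bh / 2), 0), input_size)
      rows[[a]] <- data.frame(class = best[keep] - 1L, score = score[keep],
                              x1 = x1[keep], y1 = y1[keep],
                              x2 = x2[keep], y2 = y2[keep])
    }
    out[[s]] <- do.call(rbind, rows)
  }
  dets <- do.call(rbind, out)
  if (is.null(dets)) dets <- empty_detections()
  dets <- dets[dets$x2 > dets$x1 & dets$y2 > dets$y1, , drop = FALSE]
  dets[order(-dets$score), , drop = FALSE]
}

empty_detections <- function() {
  data.frame(class = integer(0), score = numeric(0), x1 = numeric(0),
             y1 = numeric(0), x2 = numeric(0), y2 = numeric(0))
}

#' Count learnable parameters
#' @param model a [build_model()] result
#' @return integer count of learnable scalars (batch statistics excluded)
#' @export
count_parameters <- function(model) {
  sum(vapply(model$reg$params, function(p) length(p$value), numeric(1)))
}

#' Forward-pass cost in GFLOPs
#'
#' Runs one forward pass at the given input size and reports twice the
#' convolution multiply-accumulate count divided by 1e9.
#'
#' @param model a [build_model()] result
#' @param input_size square input in pixels, divisible by 32
#' @return numeric GFLOPs
#' @export
count_flops <- function(model, input_size = model$cfg$input_size) {
  if (input_size %% 32L != 0L) stop("input_size must be divisible by 32")
  ag_stop_tape()
  ag_reset_macs()
  invisible(model$forward(ag_leaf(array(0, c(3L, input_size, input_size)))))
  2 * ag_get_macs() / 1e9
}

#' Architecture profile (parameters and GFLOPs)
#' @inheritParams count_flops
#' @return list with `parameter_count` and `gflops`
#' @export
model_profile <- function(model, input_size = model$cfg$input_size) {
  list(parameter_count = count_parameters(model),
       gflops = count_flops(model, input_size))
}

#' Plain-text architecture summary
#'
#' Traces one forward pass at a given input size and tabulates every named
#' stage with its output shape and parameter count.
#'
#' @inheritParams count_flops
#' @return data.frame with columns layer, output_shape, params
#' @export
architecture_summary <- function(model, input_size = model$cfg$input_size) {
  ag_stop_tape()
  invisible(model$forward(ag_leaf(array(0, c(3L, input_size, input_size))), trace = TRUE))
  shapes <- model$trace_env$shapes
  pn <- names(model$reg$params)
  counts <- vapply(model$reg$params, function(p) length(p$value), numeric(1))
  prefix <- sub("\\..*$", "", pn)
  stage_of <- c(stem = "b0", conv1 = "b1", csp1 = "b2", conv2 = "b3",
                csp2 = "b4", conv3 = "b5", csp3 = "b6", conv4 = "b7",
                csp4 = "b8", sppf = "b9", gsppf = "b9",
                neck.reduce1 = "h10", neck.csp1 = "h13", neck.reduce2 = "h14",
                neck.csp2 = "h17", neck.csp3 = "h20", neck.csp4 = "h23",
                head.p3 = "det", head.p4 = "det", head.p5 = "det")
  extra <- c(0, 0, sum(counts[prefix == "h18"]), sum(counts[prefix == "h21"]))
  rows <- lapply(names(shapes), function(nm) {
    pref <- stage_of[[nm]]
    n <- if (nm %in% c("head.p3", "head.p4", "head.p5")) {
      sub <- sub("^det\\.", "", nm); sub <- sub("^head\\.", "", sub)
      sum(counts[pn == paste0("det.", sub, ".w") | pn == paste0("det.", sub, ".b")])
    } else sum(counts[prefix == pref | (nm == "neck.csp3" & prefix == "h18") |
                        (nm == "neck.csp4" & prefix == "h21")])
    data.frame(layer = nm, output_shape = paste(shapes[[nm]], collapse = "x"),
               params = n)
  })
  do.call(rbind, rows)
}

#' Save a model checkpoint
#'
#' Serializes the configuration, every named weight array and the batch
#' statistics to a single file.
#' @param model a [pest_model]
#' @param path output file
#' @export
save_checkpoint <- function(model, path) {
  weights <- lapply(model$reg$params, function(p) p$value)
  states <- lapply(model$reg$states, function(s)
    list(running_mean = s$running_mean, running_var = s$running_var))
  saveRDS(list(cfg = model$cfg, weights = weights, states = states), path)
  invisible(path)
}

#' Load a model checkpoint
#' @param path file written by [save_checkpoint()]
#' @return a [pest_model] with restored weights
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$cfg)
  stopifnot(identical(sort(names(model$reg$params)), sort(names(ck$weights))))
  for (nm in names(ck$weights)) model$reg$params[[nm]]$value <- ck$weights[[nm]]
  for (nm in names(ck$states)) {
    model$reg$states[[nm]]$running_mean <- ck$states[[nm]]$running_mean
    model$reg$states[[nm]]$running_var <- ck$states[[nm]]$running_var
  }
  model
}
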