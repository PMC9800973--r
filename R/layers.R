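# Building blocks of the detector: a parameter registry plus the standard
# conv / CSP modules of the YOLOv5s lineage. Every module constructor draws
# its initial weights from the current R RNG stream, registers its leaves in
# a shared registry (so counting, SGD and checkpointing are uniform), and
# returns a forward closure over autodiff nodes.

new_param_registry <- function() {
  e <- new.env(parent = emptyenv())
  e$params <- list()
  e$states <- list()
  e
}

reg_param <- function(reg, name, value) {
  leaf <- ag_leaf(value)
  reg$params[[name]] <- leaf
  leaf
}

reg_bn_state <- function(reg, name, C) {
  st <- new.env(parent = emptyenv())
  st$running_mean <- rep(0, C)
  st$running_var <- rep(1, C)
  reg$states[[name]] <- st
  st
}

kaiming_weight <- function(cout, cin, k) {
  fan_in <- cin * k * k
  matrix(stats::rnorm(cout * fan_in, 0, sqrt(2 / fan_in)), cout, fan_in)
}

apply_act <- function(x, act, slope = 0.1) {
  switch(act,
    silu = ag_silu(x),
    leaky = ag_leaky_relu(x, slope),
    sigmoid = ag_sigmoid(x),
    none = x,
    stop("unknown activation: ", act)
  )
}

# "Convs" of the lineage: convolution (no bias) + batch norm + activation
conv_block <- function(reg, name, cin, cout, k = 1L, stride = 1L,
                       pad = NULL, act = "silu") {
  if (is.null(pad)) pad <- k %/% 2L
  w <- reg_param(reg, paste0(name, ".w"), kaiming_weight(cout, cin, k))
  g <- reg_param(reg, paste0(name, ".bn_g"), rep(1, cout))
  b <- reg_param(reg, paste0(name, ".bn_b"), rep(0, cout))
  st <- reg_bn_state(reg, paste0(name, ".bn"), cout)
  list(
    cin = cin, cout = cout,
    forward = function(x, training = FALSE) {
      y <- ag_conv2d(x, w, NULL, k = k, stride = stride, pad = pad)
      y <- ag_batchnorm(y, g, b, st, training = training)
      apply_act(y, act)
    }
  )
}

# bare convolution with bias, no norm (detection head)
plain_conv <- function(reg, name, cin, cout, k = 1L, stride = 1L,
                       pad = 0L, bias_init = rep(0, cout)) {
  w <- reg_param(reg, paste0(name, ".w"), kaiming_weight(cout, cin, k))
  b <- reg_param(reg, paste0(name, ".b"), bias_init)
  list(
    cin = cin, cout = cout,
    forward = function(x, training = FALSE) {
      ag_conv2d(x, w, b, k = k, stride = stride, pad = pad)
    }
  )
}

# residual unit of the CSP blocks
bottleneck_block <- function(reg, name, c, shortcut = TRUE) {
  cv1 <- conv_block(reg, paste0(name, ".cv1"), c, c, 1L)
  cv2 <- conv_block(reg, paste0(name, ".cv2"), c, c, 3L)
  list(forward = function(x, training = FALSE) {
    y <- cv2$forward(cv1$forward(x, training), training)
    if (shortcut) ag_add(x, y) else y
  })
}

# cross-stage-partial block (CSP1_X in the backbone with shortcuts,
# CSP2_X in the neck without)
c3_block <- function(reg, name, cin, cout, n = 1L, shortcut = TRUE) {
  ch <- cout %/% 2L
  cv1 <- conv_block(reg, paste0(name, ".cv1"), cin, ch, 1L)
  cv2 <- conv_block(reg, paste0(name, ".cv2"), cin, ch, 1L)
  cv3 <- conv_block(reg, paste0(name, ".cv3"), 2L * ch, cout, 1L)
  ms <- lapply(seq_len(n), function(i) {
    bottleneck_block(reg, sprintf("%s.m%d", name, i), ch, shortcut)
  })
  list(forward = function(x, training = FALSE) {
    y <- cv1$forward(x, training)
    for (m in ms) y <- m$forward(y, training)
    z <- cv2$forward(x, training)
    cv3$forward(ag_concat(list(y, z), 1L), training)
  })
}

# channel width scaling of the YOLOv5 family
make_divisible <- function(x, divisor = 8L) {
  as.integer(max(divisor, ceiling(x / divisor) * divisor))
}
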