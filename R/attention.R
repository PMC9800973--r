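# Coordinate-and-local attention (CLA) and its plain coordinate-attention
# (CA) ablation baseline.
#
# Given a feature map X (C x H x W), two 1-D average pools encode the map
# along height and width; the pooled vectors are concatenated along the
# spatial axis, squeezed through a shared 1x1 bottleneck (C -> C/r) with
# batch norm and Leaky ReLU, split back, expanded per direction (C/r -> C)
# and gated with a sigmoid. A parallel pointwise local-context branch
# x_l = LReLU(C2(LReLU(C1(x)))) modulates the result, giving
#   x'_c(i,j) = x_c(i,j) * g^h_c(i) * g^w_c(j) * x^l_c(i,j).
# CA is the same construction without the local-context factor.

check_feature_map <- function(x, arg = "x") {
  if (!is.numeric(x) || length(dim(x)) != 3L)
    stop(arg, " must be a numeric rank-3 array (channels x height x width)")
  if (!all(is.finite(x)))
    stop(arg, " contains non-finite values")
  invisible(x)
}

#' Parameters of the coordinate-and-local attention operator
#'
#' Creates the learnable state of a CLA/CA block: the shared 1x1 bottleneck
#' convolution (C -> C/r) with its batch-normalization statistics, the two
#' directional expansion convolutions (C/r -> C), and the two pointwise
#' local-context convolutions. All kernels are 1x1.
#'
#' @param channels number of input channels C
#' @param reduction bottleneck reduction ratio r; must divide `channels`
#' @param negative_slope Leaky ReLU slope in (0,1)
#' @param init `"kaiming"` for random initialization from the current RNG
#'   stream, `"zeros"` for all-zero weights (useful for the analytic
#'   fixed-point checks)
#' @param bounded_local if TRUE, pass the local-context factor through a
#'   sigmoid so it is bounded in (0,1); the written form of the operator
#'   leaves it unbounded (default)
#' @return an object of class `cla_params`
#' @export
cla_params <- function(channels, reduction = 32L, negative_slope = 0.1,
                       init = c("kaiming", "zeros"), bounded_local = FALSE) {
  init <- match.arg(init)
  channels <- as.integer(channels)
  if (channels < 1L) stop("channels must be >= 1")
  if (channels %% reduction != 0L)
    stop("channels (", channels, ") must be divisible by reduction (", reduction, ")")
  cr <- channels %/% as.integer(reduction)
  mk <- function(cout, cin) {
    if (init == "zeros") matrix(0, cout, cin) else kaiming_weight(cout, cin, 1L)
  }
  p <- list(
    channels = channels, reduction = as.integer(reduction),
    negative_slope = negative_slope, bounded_local = bounded_local,
    w_shared = mk(cr, channels),
    bn_gamma = rep(1, cr), bn_beta = rep(0, cr),
    bn_mean = rep(0, cr), bn_var = rep(1, cr),
    w_h = mk(channels, cr), b_h = rep(0, channels),
    w_w = mk(channels, cr), b_w = rep(0, channels),
    w_c1 = mk(cr, channels), b_c1 = rep(0, cr),
    w_c2 = mk(channels, cr), b_c2 = rep(0, channels)
  )
  class(p) <- "cla_params"
  p
}

#' Directional average pooling of a feature map
#'
#' One-dimensional average pools with kernels (1, W) and (H, 1): `z_h[c, h]`
#' is the mean of row h of channel c and `z_w[c, w]` the mean of column w.
#'
#' @param x numeric array (C x H x W), finite
#' @return list with matrices `z_h` (C x H) and `z_w` (C x W)
#' @export
directional_pool <- function(x) {
  check_feature_map(x)
  d <- dim(x)
  list(
    z_h = matrix(ag_mean_axis(ag_leaf(x), 3L)$value, d[1], d[2]),
    z_w = matrix(ag_mean_axis(ag_leaf(x), 2L)$value, d[1], d[3])
  )
}

# shared graph-mode pipeline; P holds ag_node leaves + bn state
cla_gates_graph <- function(x, P, training = FALSE) {
  d <- dim(x$value)
  C <- d[1]; H <- d[2]; W <- d[3]
  z_h <- ag_mean_axis(x, 3L)                       # C x H x 1
  z_w <- ag_reshape(ag_mean_axis(x, 2L), c(C, W, 1L))
  zz <- ag_concat(list(z_h, z_w), 2L)              # C x (H+W) x 1
  f <- ag_conv2d(zz, P$w_shared, NULL, k = 1L)
  f <- ag_batchnorm(f, P$bn_gamma, P$bn_beta, P$bn_state, training = training)
  f <- ag_leaky_relu(f, P$negative_slope)
  f_h <- slice_axis_node(f, 2L, seq_len(H))
  f_w <- slice_axis_node(f, 2L, H + seq_len(W))
  g_h <- ag_sigmoid(ag_conv2d(f_h, P$w_h, P$b_h, k = 1L))        # C x H x 1
  g_w <- ag_sigmoid(ag_conv2d(f_w, P$w_w, P$b_w, k = 1L))        # C x W x 1
  list(g_h = g_h, g_w = ag_reshape(g_w, c(C, 1L, W)))
}

slice_axis_node <- function(a, axis, idx) {
  d <- dim(a$value)
  v <- slice_axis(a$value, axis, idx)
  new_node(v, function(g) {
    full <- array(0, d)
    full <- assign_axis(full, axis, idx, g)
    add_grad(a, full)
  })
}

cla_local_graph <- function(x, P, training = FALSE) {
  y <- ag_leaky_relu(ag_conv2d(x, P$w_c1, P$b_c1, k = 1L), P$negative_slope)
  y <- ag_leaky_relu(ag_conv2d(y, P$w_c2, P$b_c2, k = 1L), P$negative_slope)
  if (isTRUE(P$bounded_local)) ag_sigmoid(y) else y
}

cla_forward_graph <- function(x, P, training = FALSE, local = TRUE) {
  g <- cla_gates_graph(x, P, training)
  out <- ag_bmul(ag_bmul(x, g$g_h), g$g_w)
  if (local) out <- ag_mul(out, cla_local_graph(x, P, training))
  out
}

# wrap a plain cla_params object as graph leaves (eval-mode BN)
cla_leaves <- function(params) {
  st <- new.env(parent = emptyenv())
  st$running_mean <- params$bn_mean
  st$running_var <- params$bn_var
  list(
    w_shared = ag_leaf(params$w_shared),
    bn_gamma = ag_leaf(params$bn_gamma), bn_beta = ag_leaf(params$bn_beta),
    bn_state = st,
    w_h = ag_leaf(params$w_h), b_h = ag_leaf(params$b_h),
    w_w = ag_leaf(params$w_w), b_w = ag_leaf(params$b_w),
    w_c1 = ag_leaf(params$w_c1), b_c1 = ag_leaf(params$b_c1),
    w_c2 = ag_leaf(params$w_c2), b_c2 = ag_leaf(params$b_c2),
    negative_slope = params$negative_slope,
    bounded_local = params$bounded_local
  )
}

check_cla_input <- function(x, params) {
  check_feature_map(x)
  if (!inherits(params, "cla_params")) stop("params must be created by cla_params()")
  if (dim(x)[1] != params$channels)
    stop("input has ", dim(x)[1], " channels but params were built for ", params$channels)
}

#' Directional attention gates
#'
#' Concatenates the transposed height profile with the width profile,
#' applies the shared bottleneck convolution, batch norm and Leaky ReLU,
#' splits the result back into the two directions and expands each with its
#' own 1x1 convolution and a sigmoid. All gate values lie strictly in (0,1).
#'
#' @param z_h,z_w pooled profiles from [directional_pool()] (C x H, C x W)
#' @param params a [cla_params()] object
#' @return list with matrices `g_h` (C x H) and `g_w` (C x W)
#' @export
coordinate_weights <- function(z_h, z_w, params) {
  if (!inherits(params, "cla_params")) stop("params must be created by cla_params()")
  C <- params$channels
  if (nrow(z_h) != C || nrow(z_w) != C)
    stop("z_h / z_w must have ", C, " rows to match params")
  H <- ncol(z_h); W <- ncol(z_w)
  P <- cla_leaves(params)
  zz <- ag_leaf(array(cbind(z_h, z_w), c(C, H + W, 1L)))
  f <- ag_conv2d(zz, P$w_shared, NULL, k = 1L)
  f <- ag_batchnorm(f, P$bn_gamma, P$bn_beta, P$bn_state)
  f <- ag_leaky_relu(f, params$negative_slope)
  f_h <- slice_axis_node(f, 2L, seq_len(H))
  f_w <- slice_axis_node(f, 2L, H + seq_len(W))
  g_h <- ag_sigmoid(ag_conv2d(f_h, P$w_h, P$b_h, k = 1L))
  g_w <- ag_sigmoid(ag_conv2d(f_w, P$w_w, P$b_w, k = 1L))
  list(g_h = matrix(g_h$value, C, H), g_w = matrix(g_w$value, C, W))
}

#' Pointwise local-context branch of CLA
#'
#' `x_l = LReLU(C2(LReLU(C1(x))))` with C1: C -> C/r and C2: C/r -> C, both
#' 1x1 convolutions; the output has the shape of the input.
#'
#' @inheritParams cla_forward
#' @return numeric array with the shape of `x`
#' @export
local_context <- function(x, params) {
  check_cla_input(x, params)
  cla_local_graph(ag_leaf(x), cla_leaves(params))$value
}

#' Coordinate-and-local attention forward pass
#'
#' Elementwise product of the input, the broadcast height gate, the
#' broadcast width gate, and the local-context factor.
#'
#' @param x numeric array (C x H x W), finite
#' @param params a [cla_params()] object with matching channel count
#' @return numeric array with the shape of `x`
#' @export
cla_forward <- function(x, params) {
  check_cla_input(x, params)
  cla_forward_graph(ag_leaf(x), cla_leaves(params), local = TRUE)$value
}

#' Plain coordinate-attention forward pass (ablation baseline)
#'
#' As [cla_forward()] but without the local-context factor:
#' `x' = x * g_h * g_w`. Because both gates are sigmoid outputs, the result
#' is elementwise no larger in magnitude than the input.
#'
#' @inheritParams cla_forward
#' @return numeric array with the shape of `x`
#' @export
ca_forward <- function(x, params) {
  check_cla_input(x, params)
  cla_forward_graph(ag_leaf(x), cla_leaves(params), local = FALSE)$value
}

# registered (trainable) CLA block for use inside the detector
cla_block <- function(reg, name, channels, reduction = 32L, slope = 0.1) {
  # fall back to a smaller reduction when C/r would vanish
  while (channels %% reduction != 0L || channels %/% reduction < 1L) {
    reduction <- reduction %/% 2L
    if (reduction < 1L) stop("no valid reduction for ", channels, " channels")
  }
  cr <- channels %/% reduction
  P <- list(
    w_shared = reg_param(reg, paste0(name, ".w_shared"), kaiming_weight(cr, channels, 1L)),
    bn_gamma = reg_param(reg, paste0(name, ".bn_g"), rep(1, cr)),
    bn_beta = reg_param(reg, paste0(name, ".bn_b"), rep(0, cr)),
    bn_state = reg_bn_state(reg, paste0(name, ".bn"), cr),
    w_h = reg_param(reg, paste0(name, ".w_h"), kaiming_weight(channels, cr, 1L)),
    b_h = reg_param(reg, paste0(name, ".b_h"), rep(0, channels)),
    w_w = reg_param(reg, paste0(name, ".w_w"), kaiming_weight(channels, cr, 1L)),
    b_w = reg_param(reg, paste0(name, ".b_w"), rep(0, channels)),
    w_c1 = reg_param(reg, paste0(name, ".w_c1"), kaiming_weight(cr, channels, 1L)),
    b_c1 = reg_param(reg, paste0(name, ".b_c1"), rep(0, cr)),
    w_c2 = reg_param(reg, paste0(name, ".w_c2"), kaiming_weight(channels, cr, 1L)),
    b_c2 = reg_param(reg, paste0(name, ".b_c2"), rep(0, channels)),
    negative_slope = slope, bounded_local = FALSE
  )
  list(forward = function(x, training = FALSE) {
    cla_forward_graph(x, P, training = training, local = TRUE)
  })
}
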