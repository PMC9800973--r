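# Minimal tape-based reverse-mode autodiff over base-R numeric arrays.
#
# Every differentiable quantity is an `ag_node`: an environment holding a
# numeric array ($value), an accumulated gradient ($grad, same shape, NULL
# until touched), and -- while a tape is recording -- a backward closure.
# Feature maps use CHW layout (channel, height, width); losses are length-1
# arrays. Parameters are persistent leaf nodes whose gradients survive the
# tape, which is rebuilt on every forward pass.

.ag <- new.env(parent = emptyenv())
.ag$tape <- NULL       # list of nodes in creation (topological) order
.ag$macs <- 0          # multiply-accumulate counter for profiling

ag_recording <- function() !is.null(.ag$tape)

#' Start recording a fresh autodiff tape
#'
#' Subsequent operator calls append backward closures until [ag_stop_tape()]
#' or [ag_backward()] is called. Inference-mode forwards (no tape) skip all
#' gradient bookkeeping.
#' @return invisibly, NULL
#' @keywords internal
ag_start_tape <- function() {
  .ag$tape <- vector("list", 0L)
  invisible(NULL)
}

ag_stop_tape <- function() {
  .ag$tape <- NULL
  invisible(NULL)
}

ag_reset_macs <- function() .ag$macs <- 0
ag_get_macs <- function() .ag$macs

new_node <- function(value, backward = NULL) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  class(n) <- "ag_node"
  if (!is.null(backward) && ag_recording()) {
    n$backward <- backward
    .ag$tape[[length(.ag$tape) + 1L]] <- n
  }
  n
}

is_node <- function(x) inherits(x, "ag_node")

#' Wrap a numeric array as an autodiff leaf
#' @param value numeric array (any shape)
#' @return an `ag_node`
#' @keywords internal
ag_leaf <- function(value) new_node(value)

#' Value of an autodiff node (or passthrough for plain arrays)
#' @param x node or array
#' @keywords internal
ag_value <- function(x) if (is_node(x)) x$value else x

add_grad <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

#' Run backpropagation from a scalar node
#'
#' Seeds the output gradient with 1 and sweeps the recorded tape in reverse,
#' accumulating into every upstream node (including persistent parameter
#' leaves). Stops the tape.
#' @param node scalar `ag_node` (length-1 value)
#' @keywords internal
ag_backward <- function(node) {
  stopifnot(is_node(node), length(node$value) == 1L)
  tape <- .ag$tape
  .ag$tape <- NULL
  node$grad <- array(1, dim = dim(node$value) %||% 1L)
  for (i in rev(seq_along(tape))) {
    n <- tape[[i]]
    if (!is.null(n$grad) && !is.null(n$backward)) n$backward(n$grad)
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- elementwise arithmetic ------------------------------------------------

ag_add <- function(a, b) {
  av <- a$value; bv <- b$value
  new_node(av + bv, function(g) { add_grad(a, g); add_grad(b, g) })
}

ag_sub <- function(a, b) {
  new_node(a$value - b$value, function(g) { add_grad(a, g); add_grad(b, -g) })
}

ag_mul <- function(a, b) {
  av <- a$value; bv <- b$value
  new_node(av * bv, function(g) { add_grad(a, g * bv); add_grad(b, g * av) })
}

ag_div <- function(a, b) {
  av <- a$value; bv <- b$value
  new_node(av / bv, function(g) {
    add_grad(a, g / bv)
    add_grad(b, -g * av / (bv * bv))
  })
}

# scale/shift by plain constants
ag_scale <- function(a, k, shift = 0) {
  new_node(a$value * k + shift, function(g) add_grad(a, g * k))
}

ag_square <- function(a) ag_mul(a, a)

ag_sqrt <- function(a) {
  y <- sqrt(a$value)
  new_node(y, function(g) add_grad(a, g * 0.5 / pmax(y, 1e-12)))
}

ag_exp <- function(a) {
  y <- exp(a$value)
  new_node(y, function(g) add_grad(a, g * y))
}

# elementwise min/max against node or constant; ties route to `a`
ag_pmax <- function(a, b) {
  bv <- ag_value(b)
  y <- pmax(a$value, bv)
  sel <- a$value >= bv
  new_node(y, function(g) {
    add_grad(a, g * sel)
    if (is_node(b)) add_grad(b, g * (!sel))
  })
}

ag_pmin <- function(a, b) {
  bv <- ag_value(b)
  y <- pmin(a$value, bv)
  sel <- a$value <= bv
  new_node(y, function(g) {
    add_grad(a, g * sel)
    if (is_node(b)) add_grad(b, g * (!sel))
  })
}

ag_clamp_min <- function(a, lo) ag_pmax(a, array(lo, dim = dim(a$value) %||% length(a$value)))

# ---- activations -----------------------------------------------------------

ag_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$value))
  new_node(s, function(g) add_grad(a, g * s * (1 - s)))
}

ag_silu <- function(a) {
  s <- 1 / (1 + exp(-a$value))
  new_node(a$value * s, function(g) add_grad(a, g * s * (1 + a$value * (1 - s))))
}

ag_leaky_relu <- function(a, slope = 0.1) {
  pos <- a$value >= 0
  new_node(ifelse_arr(pos, a$value, a$value * slope),
           function(g) add_grad(a, g * ifelse_arr(pos, 1, slope)))
}

ag_relu <- function(a) {
  pos <- a$value > 0
  new_node(a$value * pos, function(g) add_grad(a, g * pos))
}

ifelse_arr <- function(test, yes, no) {
  out <- yes * test + no * (!test)
  dim(out) <- dim(test)
  out
}

# ---- broadcast multiply (dims equal or 1) ----------------------------------

# multiply a CHW node by a gate whose dims are each either equal or 1;
# gradient to the gate is summed over broadcast axes
ag_bmul <- function(x, gate) {
  xd <- dim(x$value); gd <- dim(gate$value)
  stopifnot(length(xd) == length(gd), all(gd == xd | gd == 1L))
  gv <- expand_to(gate$value, xd)
  new_node(x$value * gv, function(g) {
    add_grad(x, g * gv)
    gg <- g * x$value
    add_grad(gate, reduce_to(gg, gd))
  })
}

expand_to <- function(a, target) {
  ad <- dim(a)
  if (all(ad == target)) return(a)
  out <- a
  for (ax in seq_along(target)) {
    if (ad[ax] == 1L && target[ax] > 1L) {
      od <- dim(out)
      perm <- c(ax, seq_along(target)[-ax])
      tmp <- aperm(out, perm)
      tmp <- array(rep(as.vector(tmp), each = target[ax]), c(target[ax], od[-ax]))
      out <- aperm(tmp, order(perm))
    }
  }
  out
}

reduce_to <- function(a, target) {
  ad <- dim(a)
  if (all(ad == target)) return(a)
  out <- a
  for (ax in seq_along(target)) {
    if (target[ax] == 1L && dim(out)[ax] > 1L) {
      out <- slice_axis_sum(out, ax)
    }
  }
  out
}

# ---- shape ops -------------------------------------------------------------

ag_reshape <- function(a, newdim) {
  od <- dim(a$value)
  v <- a$value
  dim(v) <- newdim
  new_node(v, function(g) { dim(g) <- od; add_grad(a, g) })
}

# concatenate along an axis (CHW nodes)
ag_concat <- function(nodes, axis) {
  vals <- lapply(nodes, function(n) n$value)
  dims <- lapply(vals, dim)
  sizes <- vapply(dims, function(d) d[axis], numeric(1))
  out <- abind3(vals, axis)
  new_node(out, function(g) {
    at <- 0
    for (i in seq_along(nodes)) {
      idx <- (at + 1):(at + sizes[i])
      add_grad(nodes[[i]], slice_axis(g, axis, idx))
      at <- at + sizes[i]
    }
  })
}

abind3 <- function(vals, axis) {
  d1 <- dim(vals[[1]])
  total <- sum(vapply(vals, function(v) dim(v)[axis], numeric(1)))
  nd <- d1; nd[axis] <- total
  out <- array(0, nd)
  at <- 0
  for (v in vals) {
    k <- dim(v)[axis]
    out <- assign_axis(out, axis, (at + 1):(at + k), v)
    at <- at + k
  }
  out
}

slice_axis <- function(a, axis, idx) {
  d <- length(dim(a))
  args <- rep(list(quote(expr = )), d)
  args[[axis]] <- idx
  do.call(`[`, c(list(a), args, list(drop = FALSE)))
}

assign_axis <- function(a, axis, idx, value) {
  d <- length(dim(a))
  args <- rep(list(quote(expr = )), d)
  args[[axis]] <- idx
  do.call(`[<-`, c(list(a), args, list(value = value)))
}

# channel slice of a CHW node
ag_slice_c <- function(a, idx) {
  v <- a$value[idx, , , drop = FALSE]
  d <- dim(a$value)
  new_node(v, function(g) {
    full <- array(0, d)
    full[idx, , ] <- g
    add_grad(a, full)
  })
}

# mean over one spatial axis of a CHW node, keeping the axis at size 1
ag_mean_axis <- function(a, axis) {
  d <- dim(a$value)
  n <- d[axis]
  s <- slice_axis_sum(a$value, axis) / n
  new_node(s, function(g) add_grad(a, expand_to(g, d) / n))
}

slice_axis_sum <- function(a, axis) {
  d <- dim(a)
  perm <- c(axis, seq_along(d)[-axis])
  m <- matrix(aperm(a, perm), nrow = d[axis])
  s <- colSums(m)
  nd <- d; nd[axis] <- 1L
  aperm(array(s, c(1L, d[-axis])), order(perm))
}

# sum / mean of all elements -> scalar node
ag_sum <- function(a) {
  d <- dim(a$value) %||% length(a$value)
  new_node(array(sum(a$value), 1L), function(g) add_grad(a, array(as.numeric(g), d)))
}

ag_mean <- function(a) {
  n <- length(a$value)
  d <- dim(a$value) %||% n
  new_node(array(mean(a$value), 1L), function(g) add_grad(a, array(as.numeric(g) / n, d)))
}

# gather arbitrary flat indices of an array node into a new node shaped like idx
ag_gather <- function(a, idx) {
  d <- dim(a$value)
  v <- a$value[as.vector(idx)]
  dim(v) <- dim(idx) %||% length(idx)
  new_node(v, function(g) {
    acc <- rowsum(as.vector(g), group = as.vector(idx))
    full <- array(0, d)
    full[as.numeric(rownames(acc))] <- acc
    add_grad(a, full)
  })
}

# column subset of a matrix node
ag_cols <- function(a, j) {
  v <- a$value[, j, drop = FALSE]
  d <- dim(a$value)
  new_node(v, function(g) {
    full <- array(0, d)
    full[, j] <- g
    add_grad(a, full)
  })
}

# ---- binary cross-entropy with logits (stable primitive) -------------------

#' Mean binary cross-entropy against targets, taking logits
#'
#' Numerically stable softplus form; gradient is (sigmoid(x) - t)/N.
#' @param a logits node
#' @param target plain numeric array, same shape
#' @keywords internal
ag_bce_logits <- function(a, target) {
  x <- a$value
  loss <- pmax(x, 0) - x * target + log1p(exp(-abs(x)))
  n <- length(x)
  new_node(array(sum(loss) / n, 1L), function(g) {
    s <- 1 / (1 + exp(-x))
    add_grad(a, (s - target) * (as.numeric(g) / n))
  })
}

# ---- conv2d via im2col -----------------------------------------------------

im2col <- function(x, k, stride, pad) {
  d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]
  Ho <- (H + 2L * pad - k) %/% stride + 1L
  Wo <- (W + 2L * pad - k) %/% stride + 1L
  if (pad > 0L) {
    xp <- array(0, c(C, H + 2L * pad, W + 2L * pad))
    xp[, pad + seq_len(H), pad + seq_len(W)] <- x
  } else xp <- x
  cols <- matrix(0, C * k * k, Ho * Wo)
  for (kj in 0:(k - 1L)) {
    cj <- seq.int(kj + 1L, by = stride, length.out = Wo)
    for (ki in 0:(k - 1L)) {
      ri <- seq.int(ki + 1L, by = stride, length.out = Ho)
      blk <- xp[, ri, cj, drop = FALSE]
      cols[(kj * k + ki) * C + seq_len(C), ] <- matrix(blk, C, Ho * Wo)
    }
  }
  list(cols = cols, Ho = Ho, Wo = Wo, Hp = H + 2L * pad, Wp = W + 2L * pad)
}

col2im <- function(dcols, C, H, W, k, stride, pad, Ho, Wo) {
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  dxp <- array(0, c(C, Hp, Wp))
  for (kj in 0:(k - 1L)) {
    cj <- seq.int(kj + 1L, by = stride, length.out = Wo)
    for (ki in 0:(k - 1L)) {
      ri <- seq.int(ki + 1L, by = stride, length.out = Ho)
      blk <- array(dcols[(kj * k + ki) * C + seq_len(C), ], c(C, Ho, Wo))
      dxp[, ri, cj] <- dxp[, ri, cj, drop = FALSE] + blk
    }
  }
  if (pad > 0L) dxp[, pad + seq_len(H), pad + seq_len(W), drop = FALSE] else dxp
}

#' 2-D convolution on a CHW node
#'
#' @param x CHW node
#' @param w weight leaf: matrix (C_out x C_in*k*k), columns ordered channel
#'   fastest, then kernel row, then kernel column
#' @param b bias leaf (length C_out) or NULL
#' @param k,stride,pad kernel size, stride, symmetric zero padding
#' @keywords internal
ag_conv2d <- function(x, w, b = NULL, k = 1L, stride = 1L, pad = 0L) {
  d <- dim(x$value); C <- d[1]
  ic <- im2col(x$value, k, stride, pad)
  Cout <- nrow(w$value)
  y <- w$value %*% ic$cols
  if (!is.null(b)) y <- y + as.vector(b$value)
  .ag$macs <- .ag$macs + as.double(Cout) * nrow(ic$cols) * ncol(ic$cols)
  out <- array(y, c(Cout, ic$Ho, ic$Wo))
  if (!ag_recording()) return(new_node(out))
  cols <- ic$cols
  new_node(out, function(g) {
    gm <- matrix(g, Cout, ic$Ho * ic$Wo)
    add_grad(w, gm %*% t(cols))
    if (!is.null(b)) add_grad(b, rowSums(gm))
    dcols <- crossprod(w$value, gm)
    add_grad(x, col2im(dcols, C, d[2], d[3], k, stride, pad, ic$Ho, ic$Wo))
  })
}

# ---- batch normalization ---------------------------------------------------

#' Batch normalization over the spatial extent of a CHW node
#'
#' Training mode uses per-call statistics over H*W and updates `state`
#' (an environment with running_mean / running_var) in place; eval mode
#' normalizes with the stored running statistics, unless the global
#' `.ag$bn_force_batch_stats` flag requests per-call (instance) statistics
#' without updating the running averages — the inference mode of networks
#' trained one image at a time.
#' @keywords internal
ag_batchnorm <- function(x, gamma, beta, state, training = FALSE,
                         momentum = 0.1, eps = 1e-5) {
  d <- dim(x$value); C <- d[1]; N <- d[2] * d[3]
  xm <- matrix(x$value, C, N)
  if (training || isTRUE(.ag$bn_force_batch_stats)) {
    mu <- rowMeans(xm)
    va <- rowMeans((xm - mu)^2)
    if (training) {
      state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
      state$running_var  <- (1 - momentum) * state$running_var + momentum * va * N / max(N - 1, 1)
    }
  } else {
    mu <- state$running_mean
    va <- state$running_var
  }
  used_batch <- training || isTRUE(.ag$bn_force_batch_stats)
  gv <- as.vector(gamma$value)
  istd <- 1 / sqrt(va + eps)
  xhat <- (xm - mu) * istd
  y <- array(gv * xhat + as.vector(beta$value), d)
  new_node(y, function(g) {
    gm <- matrix(g, C, N)
    add_grad(gamma, rowSums(gm * xhat))
    add_grad(beta, rowSums(gm))
    if (used_batch) {
      gxh <- gm * gv
      dx <- istd * (gxh - rowMeans(gxh) - xhat * rowMeans(gxh * xhat))
    } else {
      dx <- gm * (gv * istd)
    }
    add_grad(x, array(dx, d))
  })
}

# ---- max pooling (stride 1, same padding) ----------------------------------

#' Same-size max pooling of a CHW node (odd kernel, stride 1)
#' @keywords internal
ag_maxpool_same <- function(x, k) {
  stopifnot(k %% 2L == 1L)
  p <- (k - 1L) %/% 2L
  d <- dim(x$value); C <- d[1]; H <- d[2]; W <- d[3]
  Hp <- H + 2L * p; Wp <- W + 2L * p
  xp <- array(-Inf, c(C, Hp, Wp))
  xp[, p + seq_len(H), p + seq_len(W)] <- x$value
  idxp <- array(seq_len(C * Hp * Wp), c(C, Hp, Wp))
  best <- array(-Inf, d)
  barg <- array(0L, d)
  for (dj in 0:(k - 1L)) {
    cj <- dj + seq_len(W)
    for (di in 0:(k - 1L)) {
      ri <- di + seq_len(H)
      cand <- xp[, ri, cj, drop = FALSE]
      upd <- cand > best
      best[upd] <- cand[upd]
      ci <- idxp[, ri, cj, drop = FALSE]
      barg[upd] <- ci[upd]
    }
  }
  new_node(best, function(g) {
    acc <- rowsum(as.vector(g), group = as.vector(barg))
    gp <- array(0, c(C, Hp, Wp))
    gp[as.numeric(rownames(acc))] <- acc
    add_grad(x, gp[, p + seq_len(H), p + seq_len(W), drop = FALSE])
  })
}

# ---- nearest-neighbour 2x upsample -----------------------------------------

ag_upsample2 <- function(x) {
  d <- dim(x$value); C <- d[1]; H <- d[2]; W <- d[3]
  y <- x$value[, rep(seq_len(H), each = 2L), rep(seq_len(W), each = 2L), drop = FALSE]
  new_node(y, function(g) {
    r <- array(g, c(C, 2L, H, 2L, W))
    s <- r[, 1L, , , , drop = FALSE] + r[, 2L, , , , drop = FALSE]
    dim(s) <- c(C, H, 2L, W)
    s2 <- s[, , 1L, , drop = FALSE] + s[, , 2L, , drop = FALSE]
    dim(s2) <- c(C, H, W)
    add_grad(x, s2)
  })
}
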