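# Multi-scale max pooling on the deepest feature map: classical parallel
# SPP, its cascaded equivalent SPPF, and the grouped cascade GSPPF.
#
# All pooling stages use odd kernels at stride 1 with same-padding, so the
# spatial size never changes. Three cascaded k=5 pools have the same
# receptive fields as parallel pools of kernel 5, 9 and 13, which is the
# structural basis of the SPPF == SPP equivalence checked in the tests.
# GSPPF splits the (post-entry-conv) map into four equal channel groups
# v_1..v_4 and applies small SPPF blocks in a cumulative cascade:
#   y_1 = v_1,  y_2 = SPPF_2(v_2),  y_i = SPPF_i(v_i + y_{i-1}), i in {3,4},
# then concatenates y_1..y_4 and fuses with an exit convolution.

#' Configuration and weights of the pooling modules
#'
#' Holds the max-pool kernel size, the group count of the grouped cascade,
#' and the weights of every convolution involved: the SPPF entry/exit convs
#' (`cin -> cin/2`, `2*cin -> cout`), the GSPPF entry conv (`cin -> cin`),
#' one internal SPPF per cascaded group (`cin/4 -> cin/4`, hidden width
#' `cin/8`) and the GSPPF exit conv (`cin -> cout`). Convolutions are
#' "Convs" blocks (conv + batch norm + SiLU); batch statistics default to
#' the identity normalization.
#'
#' @param cin input channel count
#' @param cout output channel count (defaults to `cin`)
#' @param kernel odd max-pool kernel size
#' @param group_count number of channel groups of the grouped cascade
#' @param init `"kaiming"` (random, current RNG stream) or `"zeros"`
#' @return an object of class `pooling_config`
#' @export
pooling_config <- function(cin, cout = cin, kernel = 5L, group_count = 4L,
                           init = c("kaiming", "zeros")) {
  init <- match.arg(init)
  kernel <- as.integer(kernel)
  if (kernel %% 2L != 1L || kernel < 1L)
    stop("pooling kernel must be an odd positive integer, got ", kernel)
  cin <- as.integer(cin); cout <- as.integer(cout)
  group_count <- as.integer(group_count)
  mk <- function(co, ci) if (init == "zeros") matrix(0, co, ci) else kaiming_weight(co, ci, 1L)
  convs <- function(co, ci) list(w = mk(co, ci), bn_g = rep(1, co), bn_b = rep(0, co),
                                 bn_mean = rep(0, co), bn_var = rep(1, co))
  half <- max(1L, cin %/% 2L)
  cfg <- list(
    cin = cin, cout = cout, kernel = kernel, group_count = group_count,
    sppf_cv1 = convs(half, cin),
    sppf_cv2 = convs(cout, half * 4L),
    gsppf = NULL
  )
  if (cin %% group_count == 0L) {
    gc <- cin %/% group_count
    gh <- max(1L, gc %/% 2L)
    cfg$gsppf <- list(
      entry = convs(cin, cin),
      groups = lapply(seq_len(group_count - 1L), function(i) {
        list(cv1 = convs(gh, gc), cv2 = convs(gc, gh * 4L))
      }),
      exit = convs(cout, cin)
    )
  }
  class(cfg) <- "pooling_config"
  cfg
}

convs_leaves <- function(cw) {
  st <- new.env(parent = emptyenv())
  st$running_mean <- cw$bn_mean
  st$running_var <- cw$bn_var
  list(w = ag_leaf(cw$w), g = ag_leaf(cw$bn_g), b = ag_leaf(cw$bn_b), st = st)
}

convs_apply <- function(x, L, training = FALSE) {
  y <- ag_conv2d(x, L$w, NULL, k = 1L)
  y <- ag_batchnorm(y, L$g, L$b, L$st, training = training)
  ag_silu(y)
}

sppf_graph_with <- function(x, cv1, cv2, kernel, training = FALSE) {
  y0 <- convs_apply(x, cv1, training)
  y1 <- ag_maxpool_same(y0, kernel)
  y2 <- ag_maxpool_same(y1, kernel)
  y3 <- ag_maxpool_same(y2, kernel)
  convs_apply(ag_concat(list(y0, y1, y2, y3), 1L), cv2, training)
}

#' Spatial pyramid pooling fast (cascaded form)
#'
#' Entry conv halves the channels, three cascaded same-size max pools of the
#' configured kernel follow, the four maps are concatenated and the exit
#' conv restores the configured output width. Spatial size is unchanged.
#'
#' @param x numeric array (C x H x W), finite
#' @param cfg a [pooling_config()] with `cin == dim(x)[1]`
#' @return numeric array (cout x H x W)
#' @export
sppf <- function(x, cfg) {
  check_feature_map(x)
  stopifnot(inherits(cfg, "pooling_config"))
  if (dim(x)[1] != cfg$cin) stop("input has ", dim(x)[1], " channels, config expects ", cfg$cin)
  sppf_graph_with(ag_leaf(x), convs_leaves(cfg$sppf_cv1), convs_leaves(cfg$sppf_cv2),
                  cfg$kernel)$value
}

#' Spatial pyramid pooling (parallel reference form)
#'
#' Identity branch plus parallel same-size max pools with the given odd
#' kernels, concatenated and fused with the same entry/exit convolutions as
#' [sppf()]. With kernels `c(5, 9, 13)` and shared weights this equals the
#' cascaded form exactly.
#'
#' @param x numeric array (C x H x W), finite
#' @param kernels vector of odd pool kernel sizes
#' @param cfg a [pooling_config()]; its entry/exit weights are reused
#' @return numeric array (cout x H x W)
#' @export
spp <- function(x, kernels, cfg) {
  check_feature_map(x)
  stopifnot(inherits(cfg, "pooling_config"))
  if (any(kernels %% 2L != 1L)) stop("all SPP kernels must be odd, got ",
                                     paste(kernels, collapse = ", "))
  cv1 <- convs_leaves(cfg$sppf_cv1)
  y0 <- convs_apply(ag_leaf(x), cv1)
  branches <- c(list(y0), lapply(kernels, function(k) {
    if (k == 1L) y0 else ag_maxpool_same(y0, as.integer(k))
  }))
  nb <- length(branches)
  cw2 <- cfg$sppf_cv2
  need <- nb * dim(y0$value)[1]
  if (ncol(cw2$w) != need) cw2$w <- cw2$w[, seq_len(need), drop = FALSE]
  convs_apply(ag_concat(branches, 1L), convs_leaves(cw2))$value
}

gsppf_graph <- function(v, G, kernel, group_count, training = FALSE,
                        identity_hook = FALSE) {
  x <- convs_apply(v, G$entry, training)
  C <- dim(x$value)[1]
  gc <- C %/% group_count
  groups <- lapply(seq_len(group_count), function(i) {
    ag_slice_c(x, (i - 1L) * gc + seq_len(gc))
  })
  ys <- vector("list", group_count)
  ys[[1L]] <- groups[[1L]]
  for (i in 2:group_count) {
    inp <- if (i == 2L) groups[[i]] else ag_add(groups[[i]], ys[[i - 1L]])
    ys[[i]] <- if (identity_hook) inp else
      sppf_graph_with(inp, G$groups[[i - 1L]]$cv1, G$groups[[i - 1L]]$cv2,
                      kernel, training)
  }
  convs_apply(ag_concat(ys, 1L), G$exit, training)
}

#' Grouped spatial-pyramid-pooling cascade
#'
#' After the entry conv the map is split into `group_count` equal channel
#' groups; the first passes through, each later group is pooled by its own
#' small SPPF after adding the previous group's output (from the third
#' group on), and the concatenated results are fused by the exit conv.
#'
#' @param v numeric array (C x H x W); C must be divisible by `group_count`
#' @param cfg a [pooling_config()] built with `cin = dim(v)[1]`
#' @param identity_hook if TRUE the internal SPPF blocks are replaced by the
#'   identity, reducing the cascade to cumulative group sums (test hook)
#' @return numeric array (cout x H x W)
#' @export
gsppf_forward <- function(v, cfg, identity_hook = FALSE) {
  check_feature_map(v, "v")
  stopifnot(inherits(cfg, "pooling_config"))
  C <- dim(v)[1]
  if (C != cfg$cin) stop("input has ", C, " channels, config expects ", cfg$cin)
  if (C %% cfg$group_count != 0L || is.null(cfg$gsppf))
    stop("channel count ", C, " is not divisible by group count ", cfg$group_count)
  G <- list(
    entry = convs_leaves(cfg$gsppf$entry),
    groups = lapply(cfg$gsppf$groups, function(g)
      list(cv1 = convs_leaves(g$cv1), cv2 = convs_leaves(g$cv2))),
    exit = convs_leaves(cfg$gsppf$exit)
  )
  gsppf_graph(ag_leaf(v), G, cfg$kernel, cfg$group_count,
              identity_hook = identity_hook)$value
}

# registered (trainable) pooling blocks for the detector ---------------------

sppf_block <- function(reg, name, cin, cout, k = 5L) {
  half <- cin %/% 2L
  cv1 <- conv_block(reg, paste0(name, ".cv1"), cin, half, 1L)
  cv2 <- conv_block(reg, paste0(name, ".cv2"), half * 4L, cout, 1L)
  list(forward = function(x, training = FALSE) {
    y0 <- cv1$forward(x, training)
    y1 <- ag_maxpool_same(y0, k)
    y2 <- ag_maxpool_same(y1, k)
    y3 <- ag_maxpool_same(y2, k)
    cv2$forward(ag_concat(list(y0, y1, y2, y3), 1L), training)
  })
}

gsppf_block <- function(reg, name, cin, cout, k = 5L, group_count = 4L) {
  if (cin %% group_count != 0L)
    stop("channel count ", cin, " is not divisible by group count ", group_count)
  gc <- cin %/% group_count
  gh <- max(1L, gc %/% 2L)
  entry <- conv_block(reg, paste0(name, ".entry"), cin, cin, 1L)
  inner <- lapply(seq_len(group_count - 1L), function(i) {
    sppf_block(reg, sprintf("%s.sppf%d", name, i + 1L), gc, gc, k)
  })
  exitc <- conv_block(reg, paste0(name, ".exit"), cin, cout, 1L)
  list(forward = function(x, training = FALSE) {
    xe <- entry$forward(x, training)
    groups <- lapply(seq_len(group_count), function(i)
      ag_slice_c(xe, (i - 1L) * gc + seq_len(gc)))
    ys <- vector("list", group_count)
    ys[[1L]] <- groups[[1L]]
    for (i in 2:group_count) {
      inp <- if (i == 2L) groups[[i]] else ag_add(groups[[i]], ys[[i - 1L]])
      ys[[i]] <- inner[[i - 1L]]$forward(inp, training)
    }
    exitc$forward(ag_concat(ys, 1L), training)
  })
}
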