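# Primitive blocks: Conv-BN-SiLU, depth-wise separable block, Focus stem,
# SPP, efficient channel attention; plus the closed-form convolution cost
# model that motivates the depth-wise substitution.
#
# Internal frag_* helpers graft a block onto an existing graph and return
# the graph with g$last pointing at the block output; the exported build_*
# functions wrap a fragment into a fresh standalone graph so its cost can
# be audited in isolation.

#' Closed-form cost of a normal vs depth-wise separable convolution
#'
#' For an input with `m` channels, kernel size `k`, `p` kernel slides per
#' spatial axis and `N` output kernels, a standard convolution costs
#' `Sc = m k^2 p^2 N` while the depth-wise separable factorization costs
#' `Sd = m k^2 p^2 + m p^2 N`. Their ratio is exactly `1/N + 1/k^2`,
#' independent of `m` and `p`, which is why the substitution shrinks any
#' network whose kernels satisfy `k >= 2, N >= 2`.
#'
#' @param m input channel count.
#' @param k kernel size.
#' @param p kernel-slide count per spatial axis.
#' @param N output kernel count.
#' @return list with `m, k, p, N, Sc, Sd, ratio`.
#' @export
paper_conv_cost <- function(m, k, p, N) {
  args <- c(m = m, k = k, p = p, N = N)
  if (any(args < 1) || any(args != floor(args))) {
    stop("all of m, k, p, N must be positive integers", call. = FALSE)
  }
  Sc <- m * k^2 * p^2 * N
  Sd <- m * k^2 * p^2 + m * p^2 * N
  list(m = m, k = k, p = p, N = N, Sc = Sc, Sd = Sd, ratio = Sd / Sc)
}

# ---- fragment builders ----------------------------------------------------

# conv2d -> batchnorm -> silu
frag_cbs <- function(g, from, c_in, c_out, k = 1L, stride = 1L) {
  stopifnot(k %in% c(1L, 3L), stride %in% c(1L, 2L))
  g <- add_node(g, "conv2d", from, out_channels = c_out, kernel = k,
                stride = stride)
  g <- add_node(g, "batchnorm", g$last)
  add_node(g, "silu", g$last)
}

# depth-wise separable block:
# dwconv2d(k, stride) -> BN -> SiLU -> conv2d 1x1 -> BN -> SiLU
frag_dws <- function(g, from, c_in, c_out, k = 3L, stride = 1L) {
  if (k == 1L) {
    stop("depth-wise separable substitution of a 1x1 conv is the identity; refused",
         call. = FALSE)
  }
  stopifnot(k == 3L, stride %in% c(1L, 2L))
  g <- add_node(g, "dwconv2d", from, kernel = k, stride = stride)
  g <- add_node(g, "batchnorm", g$last)
  g <- add_node(g, "silu", g$last)
  g <- add_node(g, "conv2d", g$last, out_channels = c_out, kernel = 1L)
  g <- add_node(g, "batchnorm", g$last)
  add_node(g, "silu", g$last)
}

# 3x3 unit that is either a plain CBS or its depth-wise separable form
frag_c3 <- function(g, from, c_in, c_out, stride = 1L, dw = FALSE) {
  if (dw) frag_dws(g, from, c_in, c_out, 3L, stride)
  else frag_cbs(g, from, c_in, c_out, 3L, stride)
}

# Focus stem: space-to-depth (3 -> 12 channels, H,W halved) then a 3x3
# CBS to c_out. The stem convolution is always a standard convolution,
# even in depth-wise separable builds (matching the upstream tiny
# detector, and required to reproduce the published totals).
frag_focus <- function(g, from, c_out = 24L) {
  g <- add_node(g, "slice_space_to_depth", from)
  frag_cbs(g, g$last, 12L, c_out, k = 3L, stride = 1L)
}

# Spatial pyramid pooling: 1x1 reduce to c_in/2, parallel stride-1
# maxpools {5, 9, 13} plus identity, concat, 1x1 expand to c_out.
frag_spp <- function(g, from, c_in, c_out, pool_sizes = c(5L, 9L, 13L)) {
  stopifnot(c_in %% 2L == 0L)
  hidden <- c_in %/% 2L
  g <- frag_cbs(g, from, c_in, hidden, k = 1L)
  mid <- g$last
  pools <- character(length(pool_sizes))
  for (i in seq_along(pool_sizes)) {
    g <- add_node(g, "maxpool", mid, kernel = pool_sizes[[i]], stride = 1L)
    pools[[i]] <- g$last
  }
  g <- add_node(g, "concat", c(mid, pools))
  frag_cbs(g, g$last, hidden * 4L, c_out, k = 1L)
}

#' Adaptive kernel size of the efficient-channel-attention 1-D conv
#'
#' `k = odd(floor(|log2(C)/gamma + b/gamma|))` with `gamma = 2`, `b = 1`:
#' the nearest odd size to half the channel log, so attention coverage
#' grows slowly with width (3 neighbouring channels at C = 96, 5 at
#' C = 384).
#'
#' @param channels channel count C.
#' @param gamma,b adaptation constants.
#' @return odd integer kernel size.
#' @export
eca_kernel_size <- function(channels, gamma = 2, b = 1) {
  stopifnot(channels >= 1)
  t <- floor(abs(log2(channels) + b) / gamma)
  k <- as.integer(if (t %% 2 == 1) t else t + 1)
  max(k, 1L)
}

# Efficient channel attention: global average pool -> channel-wise 1-D
# conv (adaptive odd kernel) -> sigmoid -> channel-wise rescale of the
# input feature map. Adds exactly k parameters.
frag_eca <- function(g, from, channels) {
  k <- eca_kernel_size(channels)
  g <- add_node(g, "global_avg_pool", from)
  g <- add_node(g, "conv1d_channelwise", g$last, kernel = k)
  g <- add_node(g, "sigmoid", g$last)
  add_node(g, "mul", c(from, g$last))
}

# ---- standalone wrappers ---------------------------------------------------

wrap_frag <- function(c_in, hw, frag_fn, outputs_last = TRUE) {
  g <- net_graph(c(c_in, hw, hw))
  g <- frag_fn(g, graph_input())
  if (outputs_last) g$outputs <- g$last
  g
}

#' Build a standalone Conv-BN-SiLU block
#' @param c_in,c_out channel counts.
#' @param k kernel size (1 or 3).
#' @param stride stride (1 or 2).
#' @param hw input spatial size used for FLOP audits.
#' @return a `netgraph`.
#' @export
build_cbs <- function(c_in, c_out, k = 1L, stride = 1L, hw = 80L) {
  wrap_frag(c_in, hw, function(g, from) frag_cbs(g, from, c_in, c_out, k, stride))
}

#' Build a standalone depth-wise separable block
#' @inheritParams build_cbs
#' @return a `netgraph`.
#' @export
build_dws <- function(c_in, c_out, k = 3L, stride = 1L, hw = 80L) {
  wrap_frag(c_in, hw, function(g, from) frag_dws(g, from, c_in, c_out, k, stride))
}

#' Build the Focus stem (space-to-depth + 3x3 CBS)
#' @param c_out stem output channels.
#' @param hw input spatial size (must be even).
#' @return a `netgraph` on a 3-channel input.
#' @export
build_focus <- function(c_out = 24L, hw = 640L) {
  wrap_frag(3L, hw, function(g, from) frag_focus(g, from, c_out))
}

#' Build a standalone spatial-pyramid-pooling block
#' @param c_in,c_out channel counts (`c_in` must be even).
#' @param hw input spatial size.
#' @return a `netgraph`.
#' @export
build_spp <- function(c_in = 384L, c_out = 384L, hw = 20L) {
  wrap_frag(c_in, hw, function(g, from) frag_spp(g, from, c_in, c_out))
}

#' Build a standalone efficient-channel-attention block
#' @param channels feature-map channel count.
#' @param hw input spatial size.
#' @return a `netgraph`.
#' @export
build_eca <- function(channels, hw = 20L) {
  wrap_frag(channels, hw, function(g, from) frag_eca(g, from, channels))
}
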