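# Cross-stage-partial block variants. The block splits its channels into
# an untouched transition path and a residual-bottleneck path, then
# re-fuses them; the three variants differ only in bottleneck depth
# (3 = CSPNet, 2 = CSPNet_M, 1 = CSPNet_S). Transition convolutions are
# 1x1 (the standard CSP layout: this, not the 3x3 entry/exit sometimes
# drawn, reproduces the published counts exactly).

# bottleneck: 1x1 CBS (c -> c) then 3x3 unit (c -> c), optional residual
frag_bottleneck <- function(g, from, c, dw = FALSE, residual_add = TRUE) {
  entry <- from
  g <- frag_cbs(g, from, c, c, k = 1L)
  g <- frag_c3(g, g$last, c, c, stride = 1L, dw = dw)
  if (residual_add) g <- add_node(g, "add", c(entry, g$last))
  g
}

# CSP block with distinct in/out widths (the path-aggregation neck fuses
# concatenated maps, so c_in is 2x c_out there); hidden width = c_out/2
frag_csp <- function(g, from, c_in, c_out, n_bottlenecks,
                     dw = FALSE, residual_add = TRUE) {
  stopifnot(c_out %% 2L == 0L, n_bottlenecks >= 1L)
  hidden <- c_out %/% 2L
  g <- frag_cbs(g, from, c_in, hidden, k = 1L)   # transition A (untouched)
  a <- g$last
  g <- frag_cbs(g, from, c_in, hidden, k = 1L)   # transition B (bottlenecks)
  for (i in seq_len(n_bottlenecks)) {
    g <- frag_bottleneck(g, g$last, hidden, dw = dw,
                         residual_add = residual_add)
  }
  b <- g$last
  g <- add_node(g, "concat", c(b, a))
  frag_cbs(g, g$last, hidden * 2L, c_out, k = 1L)
}

#' Build a standalone CSP bottleneck
#'
#' @param c channel count (preserved end to end).
#' @param dw build the 3x3 unit as a depth-wise separable block.
#' @param residual_add include the residual shortcut (parameter-neutral).
#' @param hw input spatial size for FLOP audits.
#' @return a `netgraph`.
#' @export
build_bottleneck <- function(c, dw = FALSE, residual_add = TRUE, hw = 80L) {
  wrap_frag(c, hw, function(g, from) {
    frag_bottleneck(g, from, c, dw = dw, residual_add = residual_add)
  })
}

#' Build a cross-stage-partial block
#'
#' `n_bottlenecks = 3` is the original CSPNet, 2 is CSPNet_M, 1 is
#' CSPNet_S. At 96 channels the three standard-convolution builds count
#' 88,512 / 65,280 / 42,048 parameters and the depth-wise separable
#' builds 34,800 / 29,472 / 24,144, matching the published block sizes.
#'
#' @param channels block input/output channel count (even).
#' @param n_bottlenecks residual-block count (1, 2 or 3).
#' @param dw depth-wise separable 3x3 units.
#' @param residual_add residual shortcut inside each bottleneck.
#' @param hw input spatial size for FLOP audits (the published block
#'   table uses an 80 x 80 feature map).
#' @return a `netgraph`.
#' @export
build_cspnet <- function(channels, n_bottlenecks = 3L, dw = FALSE,
                         residual_add = TRUE, hw = 80L) {
  if (channels %% 2L != 0L) {
    stop("CSP block needs an even channel count", call. = FALSE)
  }
  if (!n_bottlenecks %in% 1:3) {
    stop("n_bottlenecks must be 1, 2 or 3", call. = FALSE)
  }
  wrap_frag(channels, hw, function(g, from) {
    frag_csp(g, from, channels, channels, n_bottlenecks,
             dw = dw, residual_add = residual_add)
  })
}
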