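# The three feature-extraction backbones: the tiny baseline and its two
# slimmed variants. All share the stage widths (24, 48, 96, 192, 384);
# they differ in whether the first (stride-4) CSP block exists and in the
# bottleneck depth of the stride-8/16 stages:
#
#   tiny : CSP depths (1, 3, 3, 1)
#   lda_m: first CSP removed, depths (-, 2, 2, 1)
#   lda_s: first CSP removed, depths (-, 1, 1, 1)
#
# In the slimmed variants the channel expansion at stride 4 is carried by
# the existing stride-2 convolution alone. Each backbone emits the
# stride-8, -16 and -32 feature maps.

backbone_depths <- function(variant) {
  switch(variant,
    tiny = c(1L, 3L, 3L, 1L),
    lda_m = c(NA_integer_, 2L, 2L, 1L),
    lda_s = c(NA_integer_, 1L, 1L, 1L),
    stop("unknown backbone variant: ", variant, call. = FALSE)
  )
}

# grafts the backbone onto g; returns g with g$backbone_outputs set to
# the three multi-scale output ids (strides 8, 16, 32)
frag_backbone <- function(g, from, variant = c("tiny", "lda_m", "lda_s"),
                          dw = FALSE) {
  variant <- match.arg(variant)
  depths <- backbone_depths(variant)
  ch <- c(24L, 48L, 96L, 192L, 384L)

  g <- frag_focus(g, from, ch[[1]])                       # stride 2
  g <- frag_c3(g, g$last, ch[[1]], ch[[2]], stride = 2L, dw = dw)  # stride 4
  if (!is.na(depths[[1]])) {
    g <- frag_csp(g, g$last, ch[[2]], ch[[2]], depths[[1]], dw = dw)
  }
  g <- frag_c3(g, g$last, ch[[2]], ch[[3]], stride = 2L, dw = dw)  # stride 8
  g <- frag_csp(g, g$last, ch[[3]], ch[[3]], depths[[2]], dw = dw)
  p3 <- g$last
  g <- frag_c3(g, g$last, ch[[3]], ch[[4]], stride = 2L, dw = dw)  # stride 16
  g <- frag_csp(g, g$last, ch[[4]], ch[[4]], depths[[3]], dw = dw)
  p4 <- g$last
  g <- frag_c3(g, g$last, ch[[4]], ch[[5]], stride = 2L, dw = dw)  # stride 32
  g <- frag_spp(g, g$last, ch[[5]], ch[[5]])
  g <- frag_csp(g, g$last, ch[[5]], ch[[5]], depths[[4]], dw = dw,
                residual_add = FALSE)
  p5 <- g$last

  g$backbone_outputs <- c(p3, p4, p5)
  g
}

#' Backbone configuration
#'
#' @param variant `"tiny"` (baseline), `"lda_m"` or `"lda_s"`.
#' @param dw build every 3x3 convolution (except the Focus stem conv) as
#'   a depth-wise separable block.
#' @return a `backbone_config` list.
#' @export
backbone_config <- function(variant = c("tiny", "lda_m", "lda_s"), dw = FALSE) {
  if (length(variant) == 1 && !variant %in% c("tiny", "lda_m", "lda_s")) {
    stop("unknown backbone variant: ", variant, call. = FALSE)
  }
  variant <- match.arg(variant)
  structure(list(variant = variant, dw = isTRUE(dw),
                 stage_channels = c(24L, 48L, 96L, 192L, 384L),
                 stage_bottlenecks = backbone_depths(variant)),
            class = "backbone_config")
}

#' Build a feature-extraction backbone
#'
#' @param cfg a [backbone_config()], or a variant name.
#' @param dw depth-wise separable build (used when `cfg` is a name).
#' @param input_size input image side length (divisible by 32).
#' @return a `netgraph` whose `outputs` are the stride-8/16/32 maps.
#' @export
build_backbone <- function(cfg = backbone_config(), dw = FALSE,
                           input_size = 640L) {
  if (is.character(cfg)) cfg <- backbone_config(cfg, dw)
  stopifnot(inherits(cfg, "backbone_config"))
  if (input_size %% 32L != 0L) {
    stop("input size must be divisible by 32", call. = FALSE)
  }
  g <- net_graph(c(3L, input_size, input_size))
  g <- frag_backbone(g, graph_input(), cfg$variant, cfg$dw)
  g$outputs <- g$backbone_outputs
  g
}

#' Output shapes of a backbone
#'
#' @param cfg a [backbone_config()] or variant name.
#' @param input_size input side length (divisible by 32).
#' @return 3 x 3 integer matrix, one row `c(channels, height, width)` per
#'   output (strides 8, 16, 32).
#' @export
forward_shapes <- function(cfg = backbone_config(), input_size = 640L) {
  if (is.character(cfg)) cfg <- backbone_config(cfg)
  if (input_size %% 32L != 0L) {
    stop("input size must be divisible by 32", call. = FALSE)
  }
  strides <- c(8L, 16L, 32L)
  out <- cbind(channels = c(96L, 192L, 384L),
               height = input_size %/% strides,
               width = input_size %/% strides)
  rownames(out) <- paste0("stride", strides)
  out
}
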