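#' @useDynLib eggcandler, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif setNames
NULL

# Node kinds understood by the auditor and the executable engine.
.NODE_KINDS <- c(
  "conv2d", "dwconv2d", "batchnorm", "silu", "sigmoid", "maxpool",
  "upsample2x", "concat", "add", "slice_space_to_depth",
  "global_avg_pool", "conv1d_channelwise", "mul"
)

# Reserved id for the graph input.
.INPUT_ID <- ".input"

#' Create an empty network graph
#'
#' A `netgraph` is a symbolic, executable description of a convolutional
#' network: an ordered set of layer nodes (kind, kernel, stride, channels,
#' upstream ids) plus an input specification. Both the exact
#' parameter/FLOP audit ([count_params()], [count_flops()]) and the
#' CPU forward/backward engine ([init_params()], [forward_graph()])
#' derive from the same graph, so the audited counts are the counts of
#' the network that actually runs.
#'
#' @param input_spec integer vector `c(channels, height, width)`.
#' @return An object of class `netgraph`.
#' @export
net_graph <- function(input_spec = c(3L, 640L, 640L)) {
  stopifnot(length(input_spec) == 3, all(input_spec >= 1))
  structure(
    list(
      nodes = list(),
      order = character(),
      outputs = character(),
      input_spec = as.integer(input_spec),
      counter = 0L
    ),
    class = "netgraph"
  )
}

#' Append a layer node to a graph
#'
#' Low-level constructor used by the block builders. `inputs` must name
#' nodes already present (or the reserved graph input). Channel
#' bookkeeping is validated at insertion time.
#'
#' @param g a `netgraph`.
#' @param kind one of the supported layer kinds.
#' @param inputs character vector of upstream node ids (use
#'   [graph_input()] for the graph input).
#' @param out_channels output channel count; inferred for pass-through
#'   kinds when `NULL`.
#' @param kernel kernel size (convolutions and pooling).
#' @param stride stride, 1 or 2.
#' @param has_bias whether a `conv2d` carries a bias vector. Only the
#'   detection-head prediction convolutions set this; everywhere else
#'   bias is folded into the following batchnorm.
#' @param id optional explicit node id; auto-generated when `NULL`.
#' @return the graph with the node appended; the new id is in `g$last`.
#' @export
add_node <- function(g, kind, inputs, out_channels = NULL,
                     kernel = 1L, stride = 1L, has_bias = FALSE,
                     id = NULL) {
  stopifnot(inherits(g, "netgraph"))
  if (!kind %in% .NODE_KINDS) {
    stop("unknown node kind: ", kind, call. = FALSE)
  }
  inputs <- as.character(inputs)
  if (length(inputs) == 0) stop("node must have at least one input", call. = FALSE)
  in_ch <- vapply(inputs, function(i) node_channels(g, i), integer(1))
  if (is.null(id)) {
    g$counter <- g$counter + 1L
    id <- sprintf("%s_%04d", kind, g$counter)
  }
  if (!is.null(g$nodes[[id]])) stop("duplicate node id: ", id, call. = FALSE)

  c_in <- in_ch[[1]]
  out_channels <- switch(kind,
    conv2d = as.integer(out_channels),
    dwconv2d = c_in,
    concat = sum(in_ch),
    as.integer(if (is.null(out_channels)) c_in else out_channels)
  )

  # structural invariants
  if (kind %in% c("batchnorm", "silu", "sigmoid", "maxpool", "upsample2x",
                  "slice_space_to_depth", "global_avg_pool",
                  "conv1d_channelwise")) {
    if (length(inputs) != 1) stop(kind, " takes exactly one input", call. = FALSE)
  }
  if (kind == "dwconv2d" && !is.null(out_channels) && out_channels != c_in) {
    stop("dwconv2d requires in_channels == out_channels (node ", id, ")",
         call. = FALSE)
  }
  if (kind %in% c("add", "mul") && length(inputs) != 2) {
    stop(kind, " takes exactly two inputs (node ", id, ")", call. = FALSE)
  }
  if (kind == "add" && length(unique(in_ch)) != 1) {
    stop("add inputs must share channel count (node ", id, ")", call. = FALSE)
  }
  if (kind == "slice_space_to_depth") out_channels <- 4L * c_in
  if (kind %in% c("conv2d", "dwconv2d") && has_bias && kind == "dwconv2d") {
    stop("dwconv2d never carries a bias", call. = FALSE)
  }

  node <- list(
    id = id, kind = kind, inputs = inputs,
    in_channels = c_in, out_channels = out_channels,
    kernel = as.integer(kernel), stride = as.integer(stride),
    has_bias = isTRUE(has_bias)
  )
  g$nodes[[id]] <- node
  g$order <- c(g$order, id)
  g$last <- id
  g
}

#' Reserved id naming the graph input tensor
#' @return the input id string.
#' @export
graph_input <- function() .INPUT_ID

node_channels <- function(g, id) {
  if (id == .INPUT_ID) return(g$input_spec[[1]])
  n <- g$nodes[[id]]
  if (is.null(n)) stop("dangling input id: ", id, call. = FALSE)
  n$out_channels
}

#' Validate the structural invariants of a graph
#'
#' Checks that every node's inputs precede it (the order is a
#' topological order by construction), that declared channel counts are
#' consistent, and that output ids exist.
#'
#' @param g a `netgraph`.
#' @return `TRUE` invisibly; errors name the offending node.
#' @export
validate_graph <- function(g) {
  stopifnot(inherits(g, "netgraph"))
  seen <- .INPUT_ID
  for (id in g$order) {
    n <- g$nodes[[id]]
    miss <- setdiff(n$inputs, seen)
    if (length(miss)) {
      stop("node ", id, " references ", paste(miss, collapse = ", "),
           " before definition", call. = FALSE)
    }
    in_ch <- vapply(n$inputs, function(i) node_channels(g, i), integer(1))
    if (n$kind == "concat" && n$out_channels != sum(in_ch)) {
      stop("concat ", id, " channel mismatch", call. = FALSE)
    }
    if (n$kind == "dwconv2d" && n$out_channels != in_ch[[1]]) {
      stop("dwconv2d ", id, " channel mismatch", call. = FALSE)
    }
    seen <- c(seen, id)
  }
  miss <- setdiff(g$outputs, g$order)
  if (length(miss)) {
    stop("output ids not in graph: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Propagate spatial shapes through a graph
#'
#' @param g a `netgraph`.
#' @param input_spec optional `c(channels, height, width)` override.
#' @return named list mapping node id to `c(channels, height, width)`.
#' @export
graph_shapes <- function(g, input_spec = NULL) {
  spec <- as.integer(if (is.null(input_spec)) g$input_spec else input_spec)
  shapes <- list()
  shapes[[.INPUT_ID]] <- spec
  for (id in g$order) {
    n <- g$nodes[[id]]
    s_in <- shapes[[n$inputs[[1]]]]
    h <- s_in[[2]]; w <- s_in[[3]]
    if (n$kind %in% c("conv2d", "dwconv2d", "maxpool") && n$stride == 2) {
      if (h %% 2L != 0L || w %% 2L != 0L) {
        stop("non-integral spatial size at node ", id, call. = FALSE)
      }
      h <- h %/% 2L; w <- w %/% 2L
    } else if (n$kind == "upsample2x") {
      h <- h * 2L; w <- w * 2L
    } else if (n$kind == "slice_space_to_depth") {
      if (h %% 2L != 0L || w %% 2L != 0L) {
        stop("space-to-depth needs even spatial dims at node ", id,
             call. = FALSE)
      }
      h <- h %/% 2L; w <- w %/% 2L
    } else if (n$kind == "global_avg_pool") {
      h <- 1L; w <- 1L
    }
    if (n$kind %in% c("concat", "add", "mul")) {
      hs <- vapply(n$inputs, function(i) shapes[[i]][[2]], integer(1))
      # mul broadcasts a (C,1,1) gate over a (C,H,W) tensor
      if (n$kind != "mul" && length(unique(hs)) != 1) {
        stop("spatial mismatch at node ", id, call. = FALSE)
      }
      h <- max(vapply(n$inputs, function(i) shapes[[i]][[2]], integer(1)))
      w <- max(vapply(n$inputs, function(i) shapes[[i]][[3]], integer(1)))
    }
    shapes[[id]] <- c(n$out_channels, h, w)
  }
  shapes
}

# per-node trainable-parameter rule; batchnorm counts its two affine
# vectors only (running statistics are buffers, not parameters)
node_params <- function(n) {
  switch(n$kind,
    conv2d = n$in_channels * n$kernel^2 * n$out_channels +
      if (n$has_bias) n$out_channels else 0L,
    dwconv2d = n$in_channels * n$kernel^2,
    batchnorm = 2L * n$out_channels,
    conv1d_channelwise = n$kernel,
    0L
  )
}

#' Count trainable parameters of a graph
#'
#' Convolutions carry no bias (it is folded into the batchnorm that
#' always follows) except detection-head prediction convolutions;
#' batchnorms contribute two affine parameters per channel; the
#' channel-attention 1-D convolution contributes its kernel weights.
#' All other kinds are parameter-free.
#'
#' @param g a `netgraph`.
#' @return A `cost_report`: list with `params_total` and `per_node`.
#' @export
count_params <- function(g) {
  validate_graph(g)
  per <- vapply(g$order, function(id) as.numeric(node_params(g$nodes[[id]])),
                numeric(1))
  structure(
    list(params_total = sum(per), per_node = setNames(per, g$order)),
    class = "cost_report"
  )
}

#' Count FLOPs of a graph at a given input size
#'
#' Convolutions are counted as 2 ops per multiply-accumulate (plus one
#' add per output element when biased). Each batchnorm and each
#' activation costs `elementwise_ops` ops per element (default 4, i.e.
#' 8 per conv-BN-activation unit); global average pooling and the
#' channel-attention gate cost one op per element; pooling, upsampling,
#' concatenation, residual adds and space-to-depth are counted as free.
#' This convention reproduces the reference model-size tables.
#'
#' @param g a `netgraph`.
#' @param input_spec optional `c(channels, height, width)` override.
#' @param elementwise_ops ops per element for batchnorm and activation
#'   nodes.
#' @return A `cost_report` with `flops_total` and `per_node`.
#' @export
count_flops <- function(g, input_spec = NULL, elementwise_ops = 4) {
  validate_graph(g)
  shapes <- graph_shapes(g, input_spec)
  per <- vapply(g$order, function(id) {
    n <- g$nodes[[id]]
    s <- shapes[[id]]
    hw <- as.numeric(s[[2]]) * s[[3]]
    switch(n$kind,
      conv2d = 2 * n$in_channels * n$kernel^2 * n$out_channels * hw +
        if (n$has_bias) n$out_channels * hw else 0,
      dwconv2d = 2 * n$in_channels * n$kernel^2 * hw,
      batchnorm = elementwise_ops * n$out_channels * hw,
      silu = elementwise_ops * n$out_channels * hw,
      sigmoid = elementwise_ops * n$out_channels * hw,
      global_avg_pool = {
        s_in <- shapes[[n$inputs[[1]]]]
        as.numeric(s_in[[1]]) * s_in[[2]] * s_in[[3]]
      },
      conv1d_channelwise = 2 * n$kernel * n$out_channels,
      mul = n$out_channels * hw,
      0
    )
  }, numeric(1))
  structure(
    list(flops_total = sum(per), per_node = setNames(per, g$order)),
    class = "cost_report"
  )
}

#' @export
print.cost_report <- function(x, ...) {
  if (!is.null(x$params_total)) {
    cat(sprintf("params_total: %s (%.3f M)\n",
                format(x$params_total, big.mark = ","),
                x$params_total / 1e6))
  }
  if (!is.null(x$flops_total)) {
    cat(sprintf("flops_total: %s (%.3f G)\n",
                format(x$flops_total, big.mark = ","),
                x$flops_total / 1e9))
  }
  invisible(x)
}

#' @export
print.netgraph <- function(x, ...) {
  cat(sprintf("netgraph: %d nodes, input %s, outputs [%s]\n",
              length(x$order), paste(x$input_spec, collapse = "x"),
              paste(x$outputs, collapse = ", ")))
  invisible(x)
}
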