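# Full detector: backbone -> (optional channel attention on each of the
# three outputs) -> path-aggregation FPN -> decoupled anchor-free head,
# plus box decode and non-maximum suppression. The FPN/head layout is the
# standard tiny-detector one at hidden width 96; the dw flag substitutes
# every 3x3 convolution network-wide (backbone, neck and head branches)
# by its depth-wise separable form.

#' Detector configuration
#'
#' The final lightweight model ("LDA") is
#' `model_config("lda_s", dw = TRUE, use_eca = TRUE)`.
#'
#' @param backbone_variant `"tiny"`, `"lda_m"` or `"lda_s"`.
#' @param dw network-wide depth-wise separable 3x3 convolutions.
#' @param use_eca insert efficient channel attention after each of the
#'   three backbone outputs.
#' @param num_classes number of object classes (fertile, infertile).
#' @param head_width hidden width of the decoupled head.
#' @param input_size input side length, divisible by 32.
#' @return a `model_config` list.
#' @export
model_config <- function(backbone_variant = c("lda_s", "lda_m", "tiny"),
                         dw = TRUE, use_eca = TRUE, num_classes = 2L,
                         head_width = 96L, input_size = 640L) {
  backbone_variant <- match.arg(backbone_variant)
  if (input_size %% 32L != 0L) {
    stop("input size must be divisible by 32", call. = FALSE)
  }
  structure(list(backbone_variant = backbone_variant, dw = isTRUE(dw),
                 use_eca = isTRUE(use_eca),
                 num_classes = as.integer(num_classes),
                 head_width = as.integer(head_width),
                 input_size = as.integer(input_size)),
            class = "model_config")
}

#' Build the full detector graph
#'
#' @param cfg a [model_config()].
#' @return a `netgraph`; `outputs` holds, per pyramid level (strides 8,
#'   16, 32), the regression (4), objectness (1) and class
#'   (`num_classes`) prediction maps, and `g$head` describes the layout.
#' @export
build_model <- function(cfg = model_config()) {
  stopifnot(inherits(cfg, "model_config"))
  dw <- cfg$dw
  w <- cfg$head_width
  g <- net_graph(c(3L, cfg$input_size, cfg$input_size))
  g <- frag_backbone(g, graph_input(), cfg$backbone_variant, dw)
  feats <- g$backbone_outputs   # channels 96 / 192 / 384
  ch <- c(96L, 192L, 384L)

  if (cfg$use_eca) {
    for (i in 1:3) {
      g <- frag_eca(g, feats[[i]], ch[[i]])
      feats[[i]] <- g$last
    }
  }

  # ---- path aggregation neck ----
  g <- frag_cbs(g, feats[[3]], ch[[3]], ch[[2]], k = 1L)  # lateral 384->192
  lat0 <- g$last
  g <- add_node(g, "upsample2x", lat0)
  g <- add_node(g, "concat", c(g$last, feats[[2]]))
  g <- frag_csp(g, g$last, 2L * ch[[2]], ch[[2]], 1L, dw = dw,
                residual_add = FALSE)
  f4 <- g$last
  g <- frag_cbs(g, f4, ch[[2]], ch[[1]], k = 1L)          # reduce 192->96
  red1 <- g$last
  g <- add_node(g, "upsample2x", red1)
  g <- add_node(g, "concat", c(g$last, feats[[1]]))
  g <- frag_csp(g, g$last, 2L * ch[[1]], ch[[1]], 1L, dw = dw,
                residual_add = FALSE)
  pan3 <- g$last                                          # stride 8, 96ch
  g <- frag_c3(g, pan3, ch[[1]], ch[[1]], stride = 2L, dw = dw)
  g <- add_node(g, "concat", c(g$last, red1))
  g <- frag_csp(g, g$last, 2L * ch[[1]], ch[[2]], 1L, dw = dw,
                residual_add = FALSE)
  pan4 <- g$last                                          # stride 16, 192ch
  g <- frag_c3(g, pan4, ch[[2]], ch[[2]], stride = 2L, dw = dw)
  g <- add_node(g, "concat", c(g$last, lat0))
  g <- frag_csp(g, g$last, 2L * ch[[2]], ch[[3]], 1L, dw = dw,
                residual_add = FALSE)
  pan5 <- g$last                                          # stride 32, 384ch

  # ---- decoupled anchor-free head ----
  pan <- c(pan3, pan4, pan5)
  outputs <- character(0)
  head <- list(strides = c(8L, 16L, 32L), levels = list())
  for (i in 1:3) {
    g <- frag_cbs(g, pan[[i]], ch[[i]], w, k = 1L)        # stem
    stem <- g$last
    g <- frag_c3(g, stem, w, w, dw = dw)
    g <- frag_c3(g, g$last, w, w, dw = dw)
    cls_feat <- g$last
    g <- add_node(g, "conv2d", cls_feat, out_channels = cfg$num_classes,
                  kernel = 1L, has_bias = TRUE)
    cls_pred <- g$last
    g <- frag_c3(g, stem, w, w, dw = dw)
    g <- frag_c3(g, g$last, w, w, dw = dw)
    reg_feat <- g$last
    g <- add_node(g, "conv2d", reg_feat, out_channels = 4L,
                  kernel = 1L, has_bias = TRUE)
    reg_pred <- g$last
    g <- add_node(g, "conv2d", reg_feat, out_channels = 1L,
                  kernel = 1L, has_bias = TRUE)
    obj_pred <- g$last
    outputs <- c(outputs, reg_pred, obj_pred, cls_pred)
    head$levels[[i]] <- list(stride = head$strides[[i]], reg = reg_pred,
                             obj = obj_pred, cls = cls_pred)
  }
  g$outputs <- outputs
  g$head <- head
  g$config <- cfg
  validate_graph(g)
  g
}

#' Decode raw head outputs into boxes
#'
#' Per cell `(gx, gy)` at stride `s` the raw regression map holds
#' `(dx, dy, dw, dh)`; the box center is `((gx + dx) s, (gy + dy) s)`
#' and its size `(exp(dw) s, exp(dh) s)`. The detection score is
#' `sigmoid(obj) * sigmoid(cls)` with the best class per cell. Boxes are
#' corner-form, 0-based pixel coordinates, clipped to the image.
#'
#' @param raw_outputs list with one element per level, each a list with
#'   arrays `reg` (H x W x 4), `obj` (H x W x 1), `cls` (H x W x C).
#' @param input_size image side length in pixels.
#' @param strides pyramid strides.
#' @return data.frame with `class_id` (0-based), `score`,
#'   `x1, y1, x2, y2`.
#' @export
decode <- function(raw_outputs, input_size, strides = c(8L, 16L, 32L)) {
  stopifnot(length(raw_outputs) == length(strides))
  out <- vector("list", length(strides))
  for (i in seq_along(strides)) {
    s <- strides[[i]]
    lv <- raw_outputs[[i]]
    d <- dim(lv$reg)
    h <- d[[1]]; wdt <- d[[2]]
    if (h != input_size %/% s || wdt != input_size %/% s) {
      stop("grid size mismatch at stride ", s, ": got ", h, "x", wdt,
           call. = FALSE)
    }
    gy <- matrix(0:(h - 1), h, wdt)        # row index -> y cell
    gx <- matrix(0:(wdt - 1), h, wdt, byrow = TRUE)
    cx <- (gx + lv$reg[, , 1]) * s
    cy <- (gy + lv$reg[, , 2]) * s
    bw <- exp(lv$reg[, , 3]) * s
    bh <- exp(lv$reg[, , 4]) * s
    obj <- 1 / (1 + exp(-lv$obj[, , 1]))
    clsdim <- dim(lv$cls)[[3]]
    clsmat <- matrix(lv$cls, h * wdt, clsdim)
    cls_sig <- 1 / (1 + exp(-clsmat))
    best <- max.col(cls_sig, ties.method = "first")
    best_p <- cls_sig[cbind(seq_len(h * wdt), best)]
    out[[i]] <- data.frame(
      class_id = best - 1L,
      score = as.vector(obj) * best_p,
      x1 = pmin(pmax(as.vector(cx - bw / 2), 0), input_size),
      y1 = pmin(pmax(as.vector(cy - bh / 2), 0), input_size),
      x2 = pmin(pmax(as.vector(cx + bw / 2), 0), input_size),
      y2 = pmin(pmax(as.vector(cy + bh / 2), 0), input_size)
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Intersection-over-union of one box against many
#'
#' @param box numeric `c(x1, y1, x2, y2)`.
#' @param boxes matrix or data.frame with columns `x1, y1, x2, y2`.
#' @return numeric vector of IoU values.
#' @export
box_iou <- function(box, boxes) {
  bx <- as.matrix(boxes[, c("x1", "y1", "x2", "y2"), drop = FALSE])
  ix1 <- pmax(box[[1]], bx[, 1]); iy1 <- pmax(box[[2]], bx[, 2])
  ix2 <- pmin(box[[3]], bx[, 3]); iy2 <- pmin(box[[4]], bx[, 4])
  inter <- pmax(ix2 - ix1, 0) * pmax(iy2 - iy1, 0)
  a1 <- (box[[3]] - box[[1]]) * (box[[4]] - box[[2]])
  a2 <- (bx[, 3] - bx[, 1]) * (bx[, 4] - bx[, 2])
  u <- a1 + a2 - inter
  unname(ifelse(u > 0, inter / u, 0))
}

#' Class-wise greedy non-maximum suppression
#'
#' Detections are filtered at `score_thresh`, then suppressed greedily
#' per class by descending score; ties break deterministically by score,
#' then box area, then `x1`.
#'
#' @param boxes data.frame from [decode()].
#' @param iou_thresh suppression IoU threshold.
#' @param score_thresh minimum score retained.
#' @return the surviving rows, sorted by descending score.
#' @export
nms <- function(boxes, iou_thresh = 0.45, score_thresh = 0.01) {
  boxes <- boxes[boxes$score >= score_thresh, , drop = FALSE]
  if (nrow(boxes) == 0) return(boxes)
  area <- (boxes$x2 - boxes$x1) * (boxes$y2 - boxes$y1)
  ord <- order(-boxes$score, -area, boxes$x1)
  boxes <- boxes[ord, , drop = FALSE]
  keep <- logical(0)
  kept_rows <- list()
  for (cl in sort(unique(boxes$class_id))) {
    b <- boxes[boxes$class_id == cl, , drop = FALSE]
    alive <- rep(TRUE, nrow(b))
    for (i in seq_len(nrow(b))) {
      if (!alive[[i]]) next
      kept_rows[[length(kept_rows) + 1L]] <- b[i, , drop = FALSE]
      if (i < nrow(b)) {
        later <- which(alive & seq_len(nrow(b)) > i)
        if (length(later)) {
          ious <- box_iou(unlist(b[i, c("x1", "y1", "x2", "y2")]),
                          b[later, , drop = FALSE])
          alive[later[ious > iou_thresh]] <- FALSE
        }
      }
    }
  }
  res <- do.call(rbind, kept_rows)
  res <- res[order(-res$score, res$x1), , drop = FALSE]
  rownames(res) <- NULL
  res
}
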