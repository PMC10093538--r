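# Shared fixtures: tiny graphs, random boxes and small synthetic
# samples, all generated in code at test time.

# a minimal conv + batchnorm graph
tiny_conv_bn_graph <- function(c_in = 3L, c_out = 24L, k = 3L, hw = 8L) {
  g <- net_graph(c(c_in, hw, hw))
  g <- add_node(g, "conv2d", graph_input(), out_channels = c_out, kernel = k)
  g <- add_node(g, "batchnorm", g$last)
  g$outputs <- g$last
  g
}

# random axis-aligned boxes inside a square image
random_boxes <- function(n, size = 100, classes = 0:1) {
  x1 <- runif(n, 0, size * 0.7)
  y1 <- runif(n, 0, size * 0.7)
  data.frame(class_id = sample(classes, n, replace = TRUE),
             x1 = x1, y1 = y1,
             x2 = x1 + runif(n, size * 0.1, size * 0.3),
             y2 = y1 + runif(n, size * 0.1, size * 0.3))
}

# independent brute-force matching oracle: enumerate every injective,
# class-consistent, IoU-feasible assignment of detections to ground
# truth and take the lexicographic maximum of assigned IoUs in score
# order (FP = -Inf at that position). Exponential; for <= 6 boxes only.
brute_force_match <- function(dets, gts, iou_thresh = 0.5) {
  dets <- dets[order(-dets$score), , drop = FALSE]
  nd <- nrow(dets); ng <- nrow(gts)
  iou_mat <- matrix(0, nd, ng)
  for (i in seq_len(nd)) {
    if (ng > 0) iou_mat[i, ] <- box_iou(unlist(dets[i, c("x1", "y1", "x2", "y2")]), gts)
  }
  feasible <- function(i, j) {
    gts$class_id[[j]] == dets$class_id[[i]] && iou_mat[i, j] >= iou_thresh
  }
  best <- NULL
  best_key <- NULL
  rec <- function(i, used, assign_vec, key) {
    if (i > nd) {
      if (is.null(best_key) || lex_gt(key, best_key)) {
        best <<- assign_vec; best_key <<- key
      }
      return(invisible())
    }
    # false positive option
    rec(i + 1L, used, c(assign_vec, NA_integer_), c(key, -Inf))
    for (j in seq_len(ng)) {
      if (!used[j] && feasible(i, j)) {
        u <- used; u[j] <- TRUE
        rec(i + 1L, u, c(assign_vec, j), c(key, iou_mat[i, j]))
      }
    }
  }
  lex_gt <- function(a, b) {
    for (t in seq_along(a)) {
      if (a[t] > b[t]) return(TRUE)
      if (a[t] < b[t]) return(FALSE)
    }
    FALSE
  }
  rec(1L, rep(FALSE, max(ng, 1L)), integer(0), numeric(0))
  data.frame(score = dets$score, class_id = dets$class_id,
             tp = !is.na(best), matched_gt = best)
}

# a small annotated synthetic sample at a network-compatible size
small_sample <- function(seed, rows = 3, cols = 5, size = 96L) {
  tr <- generate_tray(rows, cols, seed = seed, image_size = c(size, size))
  list(image = tr$image, boxes = tr$boxes)
}
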