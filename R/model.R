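# Model-level API: an `egg_detector` bundles the symbolic graph, its
# instantiated parameters and the configuration. Training is plain SGD
# with momentum and weight decay under the cosine-annealing schedule;
# prediction runs the graph forward, decodes the anchor-free head and
# applies class-wise NMS.

raw_head_outputs <- function(g, outputs) {
  lapply(g$head$levels, function(l) {
    list(reg = outputs[[l$reg]], obj = outputs[[l$obj]],
         cls = outputs[[l$cls]])
  })
}

#' Train a detector on in-memory samples
#'
#' @param model_cfg a [model_config()].
#' @param data list of samples, each `list(image = (HxWx3) array in`
#'   `[0,1], boxes = data.frame(class_id, x1, y1, x2, y2))`; image side
#'   must equal `model_cfg$input_size`.
#' @param train_cfg a [train_config()].
#' @param sched_cfg a [scheduler_config()]; its `eta_max` is taken from
#'   `train_cfg$lr` and `total_epochs` from `train_cfg$epochs`.
#' @param seed integer seed controlling initialization and shuffling.
#' @param val_data optional held-out samples; mAP@0.5 is logged every
#'   `val_every` epochs.
#' @param val_every validation period in epochs.
#' @param verbose print per-epoch progress.
#' @return an `egg_detector` with a `log` data.frame (epoch, lr, loss
#'   components, val mAP).
#' @export
train <- function(model_cfg, data, train_cfg = train_config(),
                  sched_cfg = NULL, seed = 1L, val_data = NULL,
                  val_every = 5L, verbose = FALSE) {
  stopifnot(inherits(model_cfg, "model_config"), length(data) >= 1)
  if (is.null(sched_cfg)) {
    # full-length recipe: 50-epoch restarts, 70-epoch constant tail;
    # shorter runs get one cosine cycle and a proportionally shorter tail
    ep <- train_cfg$epochs
    sched_cfg <- scheduler_config(
      eta_min = train_cfg$lr / 100, eta_max = train_cfg$lr,
      T_i = if (ep >= 100L) 50L else ep,
      total_epochs = ep,
      cosine_off_tail = min(70L, as.integer(round(ep * 70 / 600))))
  }
  g <- build_model(model_cfg)
  params <- init_params(g, seed = seed)
  vel <- lapply(params, function(p) lapply(p, function(a) a * 0))
  decay_ok <- vapply(g$order, function(id)
    g$nodes[[id]]$kind %in% c("conv2d", "dwconv2d"), logical(1))
  names(decay_ok) <- g$order

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed + 1L)

  log <- data.frame()
  n <- length(data)
  for (epoch in seq_len(train_cfg$epochs) - 1L) {
    lr <- lr_schedule(epoch, sched_cfg)
    ord <- sample.int(n)
    ep_loss <- c(total = 0, iou = 0, obj = 0, cls = 0)
    nb <- 0L
    for (b0 in seq(1L, n, by = train_cfg$batch_size)) {
      batch <- ord[b0:min(b0 + train_cfg$batch_size - 1L, n)]
      acc <- NULL
      bl <- c(total = 0, iou = 0, obj = 0, cls = 0)
      for (si in batch) {
        smp <- data[[si]]
        fwd <- forward_graph(g, smp$image, params, keep_tape = TRUE)
        raw <- raw_head_outputs(g, fwd$outputs)
        ls <- detection_loss(raw, smp$boxes, model_cfg$input_size,
                             num_classes = model_cfg$num_classes,
                             reg_weight = train_cfg$reg_weight,
                             center_radius = train_cfg$center_radius)
        go <- list()
        for (li in seq_along(g$head$levels)) {
          l <- g$head$levels[[li]]
          go[[l$reg]] <- ls$grads[[li]]$reg
          go[[l$obj]] <- ls$grads[[li]]$obj
          go[[l$cls]] <- ls$grads[[li]]$cls
        }
        bw <- backward_graph(g, fwd, params, go)
        if (is.null(acc)) acc <- bw$param_grads
        else for (id in names(bw$param_grads)) {
          for (k in names(bw$param_grads[[id]])) {
            acc[[id]][[k]] <- acc[[id]][[k]] + bw$param_grads[[id]][[k]]
          }
        }
        bl <- bl + c(ls$total, ls$components)
      }
      m <- length(batch)
      for (id in names(acc)) {
        for (k in names(acc[[id]])) {
          gk <- acc[[id]][[k]] / m
          if (k == "w" && decay_ok[[id]]) {
            gk <- gk + train_cfg$weight_decay * params[[id]][[k]]
          }
          vel[[id]][[k]] <- train_cfg$momentum * vel[[id]][[k]] + gk
          params[[id]][[k]] <- params[[id]][[k]] - lr * vel[[id]][[k]]
        }
      }
      ep_loss <- ep_loss + bl / m
      nb <- nb + 1L
    }
    ep_loss <- ep_loss / nb
    if (!all(is.finite(ep_loss))) {
      stop("training diverged at epoch ", epoch, " (non-finite loss)",
           call. = FALSE)
    }
    vmap <- NA_real_
    if (!is.null(val_data) &&
        (epoch %% val_every == val_every - 1L ||
         epoch == train_cfg$epochs - 1L)) {
      mdl <- structure(list(graph = g, params = params, config = model_cfg),
                       class = "egg_detector")
      vmap <- evaluate_model(mdl, val_data)$map
    }
    log <- rbind(log, data.frame(epoch = epoch, lr = lr,
                                 loss = ep_loss[["total"]],
                                 loss_iou = ep_loss[["iou"]],
                                 loss_obj = ep_loss[["obj"]],
                                 loss_cls = ep_loss[["cls"]],
                                 val_map = vmap))
    if (verbose) {
      message(sprintf("epoch %3d lr %.2e loss %.4f (iou %.3f obj %.3f cls %.3f)%s",
                      epoch, lr, ep_loss[["total"]], ep_loss[["iou"]],
                      ep_loss[["obj"]], ep_loss[["cls"]],
                      if (is.na(vmap)) "" else sprintf(" val mAP %.3f", vmap)))
    }
  }
  structure(list(graph = g, params = params, config = model_cfg,
                 train_config = train_cfg, sched_config = sched_cfg,
                 seed = seed, log = log),
            class = "egg_detector")
}

#' Detect eggs in one image
#'
#' @param model an `egg_detector`.
#' @param image `(H x W x 3)` array in `[0, 1]`, side equal to the model
#'   input size.
#' @param score_thresh minimum detection score.
#' @param iou_thresh NMS threshold.
#' @return data.frame `class_id, score, x1, y1, x2, y2`.
#' @export
predict_boxes <- function(model, image, score_thresh = 0.3,
                          iou_thresh = 0.45) {
  g <- model$graph
  fwd <- forward_graph(g, image, model$params, keep_tape = FALSE)
  raw <- raw_head_outputs(g, fwd$outputs)
  boxes <- decode(raw, model$config$input_size)
  nms(boxes, iou_thresh = iou_thresh, score_thresh = score_thresh)
}

#' Evaluate a detector on labelled samples
#'
#' @param model an `egg_detector`.
#' @param samples list of `list(image, boxes)` samples.
#' @param iou_thresh matching threshold for mAP.
#' @param score_thresh low evaluation-time score cut before NMS.
#' @return result of [evaluate_detections()].
#' @export
evaluate_model <- function(model, samples, iou_thresh = 0.5,
                           score_thresh = 0.01) {
  preds <- lapply(samples, function(s)
    predict_boxes(model, s$image, score_thresh = score_thresh))
  gts <- lapply(samples, function(s) s$boxes)
  evaluate_detections(preds, gts, iou_thresh = iou_thresh)
}

#' @export
print.egg_detector <- function(x, ...) {
  cp <- count_params(x$graph)
  cat(sprintf("egg_detector: %s%s%s, %.3f M params, input %d\n",
              x$config$backbone_variant,
              if (x$config$dw) " + DW" else "",
              if (x$config$use_eca) " + ECA" else "",
              cp$params_total / 1e6, x$config$input_size))
  if (!is.null(x$log) && nrow(x$log)) {
    cat(sprintf("trained %d epochs, final loss %.4f\n",
                nrow(x$log), x$log$loss[[nrow(x$log)]]))
  }
  invisible(x)
}

#' Save / load a trained detector
#'
#' The checkpoint is the flat named-parameter list plus the
#' configuration; `load_model` rebuilds the graph from the stored
#' configuration.
#'
#' @param model an `egg_detector`.
#' @param path file path.
#' @return `load_model` returns an `egg_detector`.
#' @export
save_model <- function(model, path) {
  obj <- list(params = model$params, config = model$config,
              train_config = model$train_config, seed = model$seed,
              log = model$log)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  g <- build_model(obj$config)
  structure(list(graph = g, params = obj$params, config = obj$config,
                 train_config = obj$train_config, seed = obj$seed,
                 log = obj$log),
            class = "egg_detector")
}
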