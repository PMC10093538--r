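# Training machinery: cosine-annealing learning-rate schedule with a
# constant tail, Table-style SGD defaults, anchor-free target assignment
# (center-radius rule) and the detection loss with analytic gradients
# with respect to the raw head outputs.

#' Cosine-annealing scheduler configuration
#'
#' @param eta_min minimum learning rate.
#' @param eta_max maximum (initial) learning rate.
#' @param T_i cycle length in epochs (restart period).
#' @param T_cur position within the current cycle.
#' @param total_epochs total training epochs.
#' @param cosine_off_tail number of final epochs with annealing disabled.
#' @param tail_mode learning rate used in the tail: `"eta_min"` (default,
#'   finer convergence near the optimum) or `"last"` (the last annealed
#'   value).
#' @return a `scheduler_config` list.
#' @export
scheduler_config <- function(eta_min = 1e-5, eta_max = 1e-3, T_i = 50L,
                             T_cur = 0L, total_epochs = 600L,
                             cosine_off_tail = 70L,
                             tail_mode = c("eta_min", "last")) {
  tail_mode <- match.arg(tail_mode)
  stopifnot(eta_min >= 0, eta_max >= eta_min, T_cur >= 0, T_cur <= T_i)
  structure(list(eta_min = eta_min, eta_max = eta_max, T_i = as.integer(T_i),
                 T_cur = T_cur, total_epochs = as.integer(total_epochs),
                 cosine_off_tail = as.integer(cosine_off_tail),
                 tail_mode = tail_mode),
            class = "scheduler_config")
}

#' Cosine-annealed learning rate at the scheduler's current position
#'
#' `eta = eta_min + (eta_max - eta_min) (1 + cos(pi T_cur / T_i)) / 2`:
#' the maximum at the start of a cycle, the minimum at its end.
#'
#' @param cfg a [scheduler_config()].
#' @return learning rate.
#' @export
cosine_lr <- function(cfg) {
  if (cfg$T_i <= 0) stop("cycle length T_i must be positive", call. = FALSE)
  cfg$eta_min + 0.5 * (cfg$eta_max - cfg$eta_min) *
    (1 + cos(pi * cfg$T_cur / cfg$T_i))
}

#' Learning rate for a given epoch
#'
#' Cosine annealing with warm restarts every `T_i` epochs; annealing is
#' switched off for the final `cosine_off_tail` epochs, where the rate
#' is held constant (at `eta_min`, or at the last annealed value).
#'
#' @param epoch 0-based epoch index, `< total_epochs`.
#' @param sched_cfg a [scheduler_config()].
#' @return learning rate.
#' @export
lr_schedule <- function(epoch, sched_cfg = scheduler_config()) {
  if (epoch < 0 || epoch >= sched_cfg$total_epochs) {
    stop("epoch out of range", call. = FALSE)
  }
  tail_start <- sched_cfg$total_epochs - sched_cfg$cosine_off_tail
  if (epoch >= tail_start) {
    if (sched_cfg$tail_mode == "eta_min") return(sched_cfg$eta_min)
    epoch <- tail_start - 1L
  }
  sched_cfg$T_cur <- epoch %% sched_cfg$T_i
  cosine_lr(sched_cfg)
}

#' SGD training configuration
#'
#' Defaults follow the published training recipe: SGD, initial learning
#' rate 0.001, weight decay 0.0005, momentum 0.9, 600 epochs, batch
#' size 2, 640-pixel input.
#'
#' @param lr initial (maximum) learning rate.
#' @param weight_decay L2 penalty on convolution weights.
#' @param momentum SGD momentum factor.
#' @param epochs training epochs.
#' @param batch_size images per gradient step.
#' @param input_size square input side length.
#' @param reg_weight weight of the IoU loss component.
#' @param center_radius positive-cell radius in units of stride.
#' @return a `train_config` list.
#' @export
train_config <- function(lr = 1e-3, weight_decay = 5e-4, momentum = 0.9,
                         epochs = 600L, batch_size = 2L, input_size = 640L,
                         reg_weight = 5, center_radius = 2.5) {
  structure(list(lr = lr, weight_decay = weight_decay, momentum = momentum,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 input_size = as.integer(input_size),
                 reg_weight = reg_weight, center_radius = center_radius,
                 optimizer = "SGD"),
            class = "train_config")
}

# positive cells for one level: cell centers that fall inside a GT box
# AND within center_radius strides of its center; each positive is
# assigned to the nearest-center GT
assign_targets_level <- function(gt, h, w, stride, center_radius = 2.5) {
  if (nrow(gt) == 0) {
    return(list(idx = integer(0), gt = integer(0)))
  }
  gy <- rep(0:(h - 1), times = w)
  gx <- rep(0:(w - 1), each = h)
  px <- (gx + 0.5) * stride
  py <- (gy + 0.5) * stride
  best_gt <- rep(NA_integer_, h * w)
  best_d <- rep(Inf, h * w)
  r <- center_radius * stride
  for (k in seq_len(nrow(gt))) {
    cx <- (gt$x1[[k]] + gt$x2[[k]]) / 2
    cy <- (gt$y1[[k]] + gt$y2[[k]]) / 2
    ok <- px > gt$x1[[k]] & px < gt$x2[[k]] &
          py > gt$y1[[k]] & py < gt$y2[[k]] &
          abs(px - cx) <= r & abs(py - cy) <= r
    d <- (px - cx)^2 + (py - cy)^2
    upd <- ok & d < best_d
    best_gt[upd] <- k
    best_d[upd] <- d[upd]
  }
  idx <- which(!is.na(best_gt))
  list(idx = idx, gt = best_gt[idx], gx = gx[idx], gy = gy[idx])
}

# vectorized IoU and its gradient wrt predicted corners
iou_with_grad <- function(px1, py1, px2, py2, gx1, gy1, gx2, gy2) {
  iw <- pmin(px2, gx2) - pmax(px1, gx1)
  ih <- pmin(py2, gy2) - pmax(py1, gy1)
  pos <- iw > 0 & ih > 0
  I <- ifelse(pos, iw * ih, 0)
  pa <- (px2 - px1) * (py2 - py1)
  ga <- (gx2 - gx1) * (gy2 - gy1)
  U <- pa + ga - I
  iou <- ifelse(U > 0, I / U, 0)
  dI_px1 <- ifelse(pos & px1 > gx1, -ih, 0)
  dI_px2 <- ifelse(pos & px2 < gx2, ih, 0)
  dI_py1 <- ifelse(pos & py1 > gy1, -iw, 0)
  dI_py2 <- ifelse(pos & py2 < gy2, iw, 0)
  ph <- py2 - py1; pw <- px2 - px1
  dpa_px1 <- -ph; dpa_px2 <- ph; dpa_py1 <- -pw; dpa_py2 <- pw
  dfun <- function(dI, dpa) ifelse(U > 0, (dI * (U + I) - I * dpa) / U^2, 0)
  list(iou = iou,
       dx1 = dfun(dI_px1, dpa_px1), dy1 = dfun(dI_py1, dpa_py1),
       dx2 = dfun(dI_px2, dpa_px2), dy2 = dfun(dI_py2, dpa_py2))
}

#' Anchor-free detection loss with gradients
#'
#' Positives are grid cells whose center lies inside a ground-truth box
#' and within `center_radius` strides of its center. The loss is
#' `reg_weight * sum(1 - IoU)` over positives, plus binary
#' cross-entropy on objectness over all cells (target 1 on positives)
#' and on class scores over positives, all normalized by the positive
#' count. Images without ground truth contribute the objectness term
#' only.
#'
#' @param raw_outputs list per level: arrays `reg` (HxWx4), `obj`
#'   (HxWx1), `cls` (HxWxC) of raw (pre-sigmoid) head outputs.
#' @param gt_boxes data.frame `class_id, x1, y1, x2, y2` in pixels.
#' @param input_size image side length.
#' @param strides pyramid strides.
#' @param num_classes class count.
#' @param reg_weight IoU-loss weight.
#' @param center_radius assignment radius in strides.
#' @return list with `total`, `components` (iou/obj/cls), `num_fg`, and
#'   `grads`: per level, gradient arrays for `reg`, `obj`, `cls`.
#' @export
detection_loss <- function(raw_outputs, gt_boxes, input_size,
                           strides = c(8L, 16L, 32L), num_classes = 2L,
                           reg_weight = 5, center_radius = 2.5) {
  assigns <- list()
  num_fg <- 0L
  for (i in seq_along(strides)) {
    d <- dim(raw_outputs[[i]]$reg)
    assigns[[i]] <- assign_targets_level(gt_boxes, d[[1]], d[[2]],
                                         strides[[i]], center_radius)
    num_fg <- num_fg + length(assigns[[i]]$idx)
  }
  norm <- max(num_fg, 1L)
  loss_iou <- 0; loss_obj <- 0; loss_cls <- 0
  grads <- list()
  for (i in seq_along(strides)) {
    s <- strides[[i]]
    lv <- raw_outputs[[i]]
    d <- dim(lv$reg)
    h <- d[[1]]; w <- d[[2]]
    asg <- assigns[[i]]
    g_reg <- array(0, dim(lv$reg))
    g_cls <- array(0, dim(lv$cls))

    # objectness BCE over every cell
    objv <- as.vector(lv$obj)
    tgt <- numeric(h * w)
    tgt[asg$idx] <- 1
    so <- 1 / (1 + exp(-objv))
    # stable BCE-with-logits
    loss_obj <- loss_obj +
      sum(pmax(objv, 0) - objv * tgt + log1p(exp(-abs(objv)))) / norm
    g_obj <- array((so - tgt) / norm, dim(lv$obj))

    if (length(asg$idx)) {
      idx <- asg$idx
      regm <- matrix(lv$reg, h * w, 4)
      dx <- regm[idx, 1]; dy <- regm[idx, 2]
      dwl <- regm[idx, 3]; dhl <- regm[idx, 4]
      cx <- (asg$gx + dx) * s
      cy <- (asg$gy + dy) * s
      bw <- exp(dwl) * s
      bh <- exp(dhl) * s
      gt <- gt_boxes[asg$gt, , drop = FALSE]
      ig <- iou_with_grad(cx - bw / 2, cy - bh / 2, cx + bw / 2, cy + bh / 2,
                          gt$x1, gt$y1, gt$x2, gt$y2)
      loss_iou <- loss_iou + sum(1 - ig$iou) * reg_weight / norm
      scale <- -reg_weight / norm        # d(1 - iou)/d corner
      g_dx <- scale * s * (ig$dx1 + ig$dx2)
      g_dy <- scale * s * (ig$dy1 + ig$dy2)
      g_dw <- scale * (bw / 2) * (ig$dx2 - ig$dx1)
      g_dh <- scale * (bh / 2) * (ig$dy2 - ig$dy1)
      gm <- matrix(0, h * w, 4)
      gm[idx, 1] <- g_dx; gm[idx, 2] <- g_dy
      gm[idx, 3] <- g_dw; gm[idx, 4] <- g_dh
      g_reg <- array(gm, dim(lv$reg))

      # class BCE on positives
      clsm <- matrix(lv$cls, h * w, num_classes)
      tcls <- matrix(0, length(idx), num_classes)
      tcls[cbind(seq_along(idx), gt$class_id + 1L)] <- 1
      logits <- clsm[idx, , drop = FALSE]
      sc <- 1 / (1 + exp(-logits))
      loss_cls <- loss_cls +
        sum(pmax(logits, 0) - logits * tcls + log1p(exp(-abs(logits)))) / norm
      gcm <- matrix(0, h * w, num_classes)
      gcm[idx, ] <- (sc - tcls) / norm
      g_cls <- array(gcm, dim(lv$cls))
    }
    grads[[i]] <- list(reg = g_reg, obj = g_obj, cls = g_cls)
  }
  total <- loss_iou + loss_obj + loss_cls
  if (!is.finite(total)) {
    stop("detection loss diverged (non-finite value)", call. = FALSE)
  }
  list(total = total,
       components = c(iou = loss_iou, obj = loss_obj, cls = loss_cls),
       num_fg = num_fg, grads = grads)
}
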