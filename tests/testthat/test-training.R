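test_that("cosine annealing hits its endpoints and midpoint exactly", {
  cfg <- scheduler_config(eta_min = 0, eta_max = 1e-3, T_i = 50L)
  cfg$T_cur <- 0
  expect_identical(cosine_lr(cfg), 1e-3)
  cfg$T_cur <- 50
  expect_equal(cosine_lr(cfg), 0)
  cfg$T_cur <- 25
  expect_equal(cosine_lr(cfg), 5e-4)
  expect_error(cosine_lr(scheduler_config(T_i = 1L, T_cur = 0L)$T_i <- 0L))
  bad <- scheduler_config(); bad$T_i <- 0L
  expect_error(cosine_lr(bad), "positive")
})

test_that("the schedule restarts, is monotone within a cycle, and holds a constant tail", {
  sc <- scheduler_config(eta_min = 1e-5, eta_max = 1e-3, T_i = 50L,
                         total_epochs = 600L, cosine_off_tail = 70L)
  expect_equal(lr_schedule(0, sc), 1e-3)
  # periodic with period T_i before the tail
  lrs1 <- vapply(0:49, lr_schedule, numeric(1), sched_cfg = sc)
  lrs2 <- vapply(50:99, lr_schedule, numeric(1), sched_cfg = sc)
  expect_equal(lrs1, lrs2)
  expect_true(all(diff(lrs1) < 0))
  # final 70 epochs: constant eta_min
  tail_lrs <- vapply(530:599, lr_schedule, numeric(1), sched_cfg = sc)
  expect_true(all(tail_lrs == 1e-5))
  expect_gt(lr_schedule(529, sc), 1e-5)
  expect_error(lr_schedule(600, sc), "out of range")
  expect_error(lr_schedule(-1, sc), "out of range")
  # alternative tail: hold the last annealed value
  sc2 <- scheduler_config(eta_min = 1e-5, eta_max = 1e-3, T_i = 50L,
                          total_epochs = 600L, cosine_off_tail = 70L,
                          tail_mode = "last")
  expect_equal(lr_schedule(599, sc2), lr_schedule(529, sc2))
})

test_that("detection loss is zero for a perfect saturated prediction", {
  # one GT box; craft raw outputs that decode exactly to it with
  # saturated objectness/class logits on positives and -inf elsewhere
  input_size <- 64L
  gt <- data.frame(class_id = 0L, x1 = 16, y1 = 16, x2 = 48, y2 = 48)
  dims <- list(c(8L, 8L), c(4L, 4L), c(2L, 2L))
  strides <- c(8L, 16L, 32L)
  big <- 40
  raw <- list()
  for (li in 1:3) {
    d <- dims[[li]]; s <- strides[[li]]
    reg <- array(0, c(d, 4L)); obj <- array(-big, c(d, 1L))
    cls <- array(-big, c(d, 2L))
    asg <- eggcandler:::assign_targets_level(gt, d[1], d[2], s)
    for (q in seq_along(asg$idx)) {
      gx <- asg$gx[[q]]; gy <- asg$gy[[q]]
      reg[gy + 1, gx + 1, 1] <- 32 / s - gx   # center (32, 32)
      reg[gy + 1, gx + 1, 2] <- 32 / s - gy
      reg[gy + 1, gx + 1, 3] <- log(32 / s)   # size 32
      reg[gy + 1, gx + 1, 4] <- log(32 / s)
      obj[gy + 1, gx + 1, 1] <- big
      cls[gy + 1, gx + 1, 1] <- big
    }
    raw[[li]] <- list(reg = reg, obj = obj, cls = cls)
  }
  ls <- detection_loss(raw, gt, input_size)
  expect_gt(ls$num_fg, 0)
  expect_lt(ls$total, 1e-10)
})

test_that("empty ground truth leaves only the objectness term, which vanishes
           for saturated background logits", {
  dims <- list(c(4L, 4L), c(2L, 2L), c(1L, 1L))
  raw <- lapply(dims, function(d) list(
    reg = array(0, c(d, 4L)), obj = array(-40, c(d, 1L)),
    cls = array(0, c(d, 2L))))
  gt0 <- data.frame(class_id = integer(0), x1 = numeric(0), y1 = numeric(0),
                    x2 = numeric(0), y2 = numeric(0))
  ls <- detection_loss(raw, gt0, 32L)
  expect_equal(ls$num_fg, 0)
  expect_equal(unname(ls$components[c("iou", "cls")]), c(0, 0))
  expect_lt(ls$total, 1e-10)
})

test_that("a positive cell with IoU one half contributes exactly that much", {
  # single level setup for clarity
  input_size <- 32L
  gt <- data.frame(class_id = 0L, x1 = 8, y1 = 8, x2 = 24, y2 = 24)
  dims <- list(c(4L, 4L), c(2L, 2L), c(1L, 1L))
  strides <- c(8L, 16L, 32L)
  raw <- lapply(dims, function(d) list(
    reg = array(0, c(d, 4L)), obj = array(-40, c(d, 1L)),
    cls = array(0, c(d, 2L))))
  # put an exact box with saturated logits on every positive cell,
  # except one designated cell that gets a half-IoU box
  first <- TRUE
  for (li in 1:3) {
    s <- strides[[li]]
    asg <- eggcandler:::assign_targets_level(gt, dims[[li]][1],
                                             dims[[li]][2], s)
    for (q in seq_along(asg$idx)) {
      gx <- asg$gx[[q]]; gy <- asg$gy[[q]]
      raw[[li]]$obj[gy + 1, gx + 1, 1] <- 40
      raw[[li]]$cls[gy + 1, gx + 1, 1] <- 40
      raw[[li]]$cls[gy + 1, gx + 1, 2] <- -40
      if (first) {
        # box (8,8)-(16,24): area 128, intersection 128, union 256
        raw[[li]]$reg[gy + 1, gx + 1, 1] <- 12 / s - gx
        raw[[li]]$reg[gy + 1, gx + 1, 2] <- 16 / s - gy
        raw[[li]]$reg[gy + 1, gx + 1, 3] <- log(8 / s)
        raw[[li]]$reg[gy + 1, gx + 1, 4] <- log(16 / s)
        first <- FALSE
      } else {
        raw[[li]]$reg[gy + 1, gx + 1, 1] <- 16 / s - gx
        raw[[li]]$reg[gy + 1, gx + 1, 2] <- 16 / s - gy
        raw[[li]]$reg[gy + 1, gx + 1, 3] <- log(16 / s)
        raw[[li]]$reg[gy + 1, gx + 1, 4] <- log(16 / s)
      }
    }
  }
  ls <- detection_loss(raw, gt, input_size, reg_weight = 1)
  # iou component = mean over positives of (1 - IoU); only one cell has
  # IoU 0.5, the rest are exact
  expect_equal(unname(ls$components[["iou"]]), 0.5 / ls$num_fg)
})

test_that("loss gradients match numerical differentiation", {
  set.seed(3)
  dims <- list(c(4L, 4L), c(2L, 2L), c(1L, 1L))
  raw <- lapply(dims, function(d) list(
    reg = array(rnorm(prod(d) * 4, sd = 0.5), c(d, 4L)),
    obj = array(rnorm(prod(d)), c(d, 1L)),
    cls = array(rnorm(prod(d) * 2), c(d, 2L))))
  gt <- data.frame(class_id = c(0L, 1L), x1 = c(2, 16), y1 = c(4, 18),
                   x2 = c(14, 30), y2 = c(15, 31))
  ls <- detection_loss(raw, gt, 32L)
  lf <- function(r) detection_loss(r, gt, 32L)$total
  eps <- 1e-6
  for (li in 1:3) for (part in c("reg", "obj", "cls")) {
    arr <- raw[[li]][[part]]
    for (ix in sample(length(arr), min(3, length(arr)))) {
      r2 <- raw; r2[[li]][[part]][ix] <- arr[ix] + eps
      r3 <- raw; r3[[li]][[part]][ix] <- arr[ix] - eps
      num <- (lf(r2) - lf(r3)) / (2 * eps)
      expect_equal(ls$grads[[li]][[part]][ix], num, tolerance = 1e-4)
    }
  }
})

test_that("training is deterministic and wires the schedule through", {
  cfg <- model_config("lda_s", dw = TRUE, use_eca = TRUE, input_size = 64L)
  data <- lapply(1:2, function(i) small_sample(i, rows = 2, cols = 2,
                                               size = 64L))
  tcfg <- train_config(lr = 1e-3, epochs = 2L, batch_size = 2L,
                       input_size = 64L)
  m1 <- train(cfg, data, tcfg, seed = 5)
  m2 <- train(cfg, data, tcfg, seed = 5)
  expect_identical(m1$log$loss, m2$log$loss)
  expect_identical(m1$params, m2$params)
  # the logged lr trace equals the schedule exactly
  expect_equal(m1$log$lr,
               vapply(m1$log$epoch, lr_schedule, numeric(1),
                      sched_cfg = m1$sched_config))
})
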