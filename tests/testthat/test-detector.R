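test_that("full-model parameter totals match the published sizes", {
  expect_equal(count_params(build_model(model_config("tiny", dw = FALSE,
    use_eca = FALSE)))$params_total, 5033157)
  expect_equal(count_params(build_model(model_config("tiny", dw = TRUE,
    use_eca = FALSE)))$params_total, 1991301)
  expect_equal(count_params(build_model(model_config("lda_s", dw = TRUE,
    use_eca = TRUE)))$params_total, 1934602)
})

test_that("dw and eca flags change counts exactly as expected", {
  base <- count_params(build_model(model_config("lda_s", dw = TRUE,
    use_eca = FALSE)))$params_total
  eca <- count_params(build_model(model_config("lda_s", dw = TRUE,
    use_eca = TRUE)))$params_total
  # attention on 96/192/384 channels: kernels 3 + 5 + 5
  expect_equal(eca - base, 13)
  expect_lte(eca - base, 13)
})

test_that("decode follows the anchor-free rule", {
  mk_level <- function(n, c = 2) list(reg = array(0, c(n, n, 4)),
                                      obj = array(0, c(n, n, 1)),
                                      cls = array(0, c(n, n, c)))
  raw <- list(mk_level(80), mk_level(40), mk_level(20))
  # one decorated cell: (gx = 4, gy = 3) at stride 8
  raw[[1]]$reg[4, 5, 1] <- 0.5   # row = gy + 1, col = gx + 1
  raw[[1]]$reg[4, 5, 2] <- 0.25
  d <- decode(raw, 640L)
  expect_equal(nrow(d), 80^2 + 40^2 + 20^2)   # 8,400 candidate cells
  cell <- d[with(d, which(abs(x1 - 32) < 1e-9 & abs(y1 - 22) < 1e-9)), ]
  expect_equal(cell$x1 + 4, (4 + 0.5) * 8)    # center (36, 26), w = h = 8
  expect_equal((cell$x1 + cell$x2) / 2, 36)
  expect_equal((cell$y1 + cell$y2) / 2, 26)
  expect_equal(cell$x2 - cell$x1, 8)
  # zero offsets at the origin cell: centered at (0,0), clipped
  origin <- d[1, ]
  expect_equal(c(origin$x1, origin$y1), c(0, 0))
  expect_equal(c(origin$x2, origin$y2), c(4, 4))
  expect_error(decode(raw, 320L), "grid size mismatch")
})

test_that("decode inverts box encoding on grid centers", {
  set.seed(9)
  for (rep in 1:5) {
    s <- 8; n <- 16; input <- s * n
    gx <- sample(0:(n - 1), 1); gy <- sample(0:(n - 1), 1)
    dx <- runif(1, 0.2, 0.8); dy <- runif(1, 0.2, 0.8)
    lw <- runif(1, -0.5, 0.5); lh <- runif(1, -0.5, 0.5)
    raw <- list(list(reg = array(0, c(n, n, 4)), obj = array(0, c(n, n, 1)),
                     cls = array(0, c(n, n, 2))),
                list(reg = array(0, c(n / 2, n / 2, 4)),
                     obj = array(0, c(n / 2, n / 2, 1)),
                     cls = array(0, c(n / 2, n / 2, 2))),
                list(reg = array(0, c(n / 4, n / 4, 4)),
                     obj = array(0, c(n / 4, n / 4, 1)),
                     cls = array(0, c(n / 4, n / 4, 2))))
    raw[[1]]$reg[gy + 1, gx + 1, ] <- c(dx, dy, lw, lh)
    d <- decode(raw, input)
    i <- gy + 1 + n * gx   # column-major cell order within level 1
    got <- unlist(d[i, c("x1", "y1", "x2", "y2")])
    cx <- (gx + dx) * s; cy <- (gy + dy) * s
    w <- exp(lw) * s; h <- exp(lh) * s
    want <- pmin(pmax(c(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2), 0),
                 input)
    expect_equal(unname(got), want, tolerance = 1e-6)
  }
})

test_that("nms keeps the right boxes", {
  b <- function(x1, y1, x2, y2, s, cl = 0L)
    data.frame(class_id = cl, score = s, x1 = x1, y1 = y1, x2 = x2, y2 = y2)
  # identical boxes: only the higher score survives
  two <- rbind(b(0, 0, 10, 10, 0.9), b(0, 0, 10, 10, 0.8))
  expect_equal(nms(two)$score, 0.9)
  # disjoint boxes all survive
  far <- rbind(b(0, 0, 10, 10, 0.9), b(50, 50, 60, 60, 0.8))
  expect_equal(nrow(nms(far)), 2)
  # different classes never suppress each other
  cl2 <- rbind(b(0, 0, 10, 10, 0.9, 0L), b(0, 0, 10, 10, 0.8, 1L))
  expect_equal(nrow(nms(cl2)), 2)
  # chain: A suppresses B (IoU 0.6), C overlaps A negligibly -> keep A, C
  A <- b(0, 0, 8, 8, 0.9)
  B <- b(2, 0, 10, 8, 0.8)         # IoU(A,B) = 48/80 = 0.6
  C <- b(7.5, 7.5, 15.5, 15.5, 0.7) # IoU(A,C) ~ 0.002
  expect_equal(box_iou(unlist(A[c("x1", "y1", "x2", "y2")]), B), 0.6)
  expect_lt(box_iou(unlist(A[c("x1", "y1", "x2", "y2")]), C), 0.45)
  expect_gt(box_iou(unlist(B[c("x1", "y1", "x2", "y2")]), C), 0)
  kept <- nms(rbind(A, B, C), iou_thresh = 0.45)
  expect_equal(sort(kept$score), c(0.7, 0.9))
  # score threshold filters
  expect_equal(nrow(nms(two, score_thresh = 0.95)), 0)
})

test_that("a real forward pass emits one candidate per grid cell", {
  cfg <- model_config("lda_s", dw = TRUE, use_eca = TRUE, input_size = 64L)
  g <- build_model(cfg)
  params <- init_params(g, seed = 1)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  fwd <- forward_graph(g, x, params)
  raw <- eggcandler:::raw_head_outputs(g, fwd$outputs)
  d <- decode(raw, 64L)
  expect_equal(nrow(d), 8^2 + 4^2 + 2^2)
  expect_true(all(d$score >= 0 & d$score <= 1))
  expect_true(all(d$x1 <= d$x2 & d$y1 <= d$y2))
})
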