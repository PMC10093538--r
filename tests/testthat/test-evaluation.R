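test_that("precision and recall follow their definitions", {
  expect_equal(precision(220, 0), 1.0)
  expect_equal(precision(3, 1), 0.75)
  expect_equal(precision(0, 5), 0.0)
  expect_error(precision(0, 0), "undefined")
  expect_equal(recall(7, 7), 0.5)
  expect_equal(recall(106, 0), 1.0)
  expect_equal(recall(2, 6), 0.25)
  expect_error(recall(0, 0), "ground truth")
})

test_that("greedy matching handles the canonical cases", {
  gt <- data.frame(class_id = 0L, x1 = 10, y1 = 10, x2 = 30, y2 = 30)
  # exact hit
  d1 <- data.frame(class_id = 0L, score = 0.9, x1 = 10, y1 = 10,
                   x2 = 30, y2 = 30)
  expect_true(match_detections(d1, gt)$tp)
  # two detections on one GT: only the higher score is a TP
  d2 <- rbind(d1, transform(d1, score = 0.7))
  m <- match_detections(d2, gt)
  expect_equal(m$tp, c(TRUE, FALSE))
  # class mismatch is never a TP
  d3 <- transform(d1, class_id = 1L)
  expect_false(match_detections(d3, gt)$tp)
})

test_that("greedy matching agrees with the brute-force assignment oracle", {
  set.seed(17)
  for (rep in 1:30) {
    n_gt <- sample(0:3, 1)
    n_det <- sample(1:3, 1)
    gts <- random_boxes(max(n_gt, 1), size = 60)[seq_len(n_gt), , drop = FALSE]
    dets <- random_boxes(n_det, size = 60)
    # make some detections near-copies of GTs so matches happen
    if (n_gt > 0) {
      for (i in seq_len(min(n_det, n_gt))) {
        if (runif(1) < 0.7) {
          j <- sample(n_gt, 1)
          jit <- runif(4, -3, 3)
          dets[i, c("x1", "y1", "x2", "y2")] <-
            gts[j, c("x1", "y1", "x2", "y2")] + jit
          dets$class_id[i] <- gts$class_id[j]
        }
      }
    }
    dets$score <- runif(n_det)
    got <- match_detections(dets, gts, iou_thresh = 0.5)
    want <- brute_force_match(dets, gts, iou_thresh = 0.5)
    expect_equal(got$tp, want$tp)
    expect_equal(got$matched_gt, want$matched_gt)
  }
})

test_that("average precision: unit square, zero, and the hand-worked case", {
  expect_equal(average_precision(c(0.9, 0.8), c(TRUE, TRUE), 2)$ap, 1.0)
  expect_equal(average_precision(c(0.9, 0.8), c(FALSE, FALSE), 2)$ap, 0.0)
  # 2 GTs, detections (0.9 TP), (0.8 FP), (0.7 TP):
  # envelope area = 0.5 * 1 + 0.5 * 2/3
  r <- average_precision(c(0.9, 0.8, 0.7), c(TRUE, FALSE, TRUE), 2)
  expect_equal(r$ap, 0.5 + 0.5 * 2 / 3, tolerance = 1e-12)
  expect_equal(round(r$ap, 4), 0.8333)
  expect_error(average_precision(numeric(0), logical(0), 0), "ground truth")
})

test_that("AP is invariant to monotone score rescaling", {
  set.seed(23)
  for (rep in 1:10) {
    n <- sample(3:10, 1)
    scores <- runif(n)
    tp <- runif(n) > 0.4
    n_gt <- sum(tp) + sample(0:2, 1)
    if (n_gt == 0) n_gt <- 1
    a1 <- average_precision(scores, tp, n_gt)$ap
    a2 <- average_precision(plogis(5 * scores - 2), tp, n_gt)$ap
    expect_equal(a1, a2)
  }
})

test_that("appending a low-scored duplicate FP never raises AP", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(2:8, 1)
    scores <- sort(runif(n), decreasing = TRUE)
    tp <- runif(n) > 0.3
    n_gt <- max(sum(tp), 1)
    base <- average_precision(scores, tp, n_gt)$ap
    worse <- average_precision(c(scores, min(scores) / 2), c(tp, FALSE),
                               n_gt)$ap
    expect_lte(worse, base + 1e-12)
  }
})

test_that("mAP is the arithmetic mean of class APs", {
  expect_equal(mean_ap(c(1, 1)), 1)
  expect_equal(mean_ap(0.73), 0.73)
  # the tiny-baseline row: AP (99.84, 90.00) combines to 94.92
  expect_equal(round(100 * mean_ap(c(0.9984, 0.9000)), 2), 94.92)
})

test_that("end-to-end evaluation over images produces a sane mAP", {
  gt1 <- data.frame(class_id = c(0L, 1L), x1 = c(0, 40), y1 = c(0, 40),
                    x2 = c(20, 60), y2 = c(20, 60))
  # perfect predictions on image 1, miss + false alarm on image 2
  p1 <- data.frame(class_id = c(0L, 1L), score = c(0.9, 0.85),
                   x1 = c(0, 40), y1 = c(0, 40), x2 = c(20, 60),
                   y2 = c(20, 60))
  gt2 <- data.frame(class_id = 0L, x1 = 10, y1 = 10, x2 = 30, y2 = 30)
  p2 <- data.frame(class_id = 0L, score = 0.5, x1 = 70, y1 = 70,
                   x2 = 90, y2 = 90)
  res <- evaluate_detections(list(p1, p2), list(gt1, gt2))
  expect_equal(res$per_class$infertile$ap, 1)
  expect_lt(res$per_class$fertile$ap, 1)
  expect_equal(res$map,
               mean(c(res$per_class$fertile$ap, res$per_class$infertile$ap)))
})
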