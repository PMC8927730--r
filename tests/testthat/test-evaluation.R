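# Detection metrics against hand-worked and independent oracles.

test_that("greedy matching handles the elementary cases", {
  gt <- list(boxes = matrix(c(0, 0, 10, 10), 1), classes = 1L)
  m <- match_detections(matrix(c(0, 0, 10, 10), 1), 0.9, 1L,
                        gt$boxes, gt$classes)
  expect_true(m$tp)
  # two detections on one gt: one TP, one FP
  m2 <- match_detections(rbind(c(0, 0, 10, 10), c(1, 1, 11, 11)),
                         c(0.9, 0.8), c(1L, 1L), gt$boxes, gt$classes)
  expect_equal(m2$tp, c(TRUE, FALSE))
  # class mismatch never matches
  m3 <- match_detections(matrix(c(0, 0, 10, 10), 1), 0.9, 2L,
                         gt$boxes, gt$classes)
  expect_false(m3$tp)
})

test_that("the 3-detection/2-gt worked set evaluates to the hand AP", {
  # dets (scores .9, .8, .7) with IoUs to gt1/gt2 of .8/.1, .6/.0, .0/.9:
  # flags (TP, FP, TP); PR points (1, .5), (.5, .5), (2/3, 1); 101-point
  # interpolated AP = (51 * 1 + 50 * 2/3) / 101 = 253/303
  gt <- list(boxes = rbind(c(0, 0, 10, 10), c(40, 40, 50, 50)),
             classes = c(1L, 1L))
  # construct boxes with the required IoUs analytically: same-width boxes
  # sliding vertically give IoU (h - s) / (h + s)
  shift_for <- function(iou, h = 10) h * (1 - iou) / (1 + iou)
  det1 <- c(0, shift_for(0.8), 10, 10 + shift_for(0.8))      # IoU .8 to gt1
  det2 <- c(0, shift_for(0.6), 10, 10 + shift_for(0.6))      # IoU .6 to gt1
  det3 <- c(40, 40 + shift_for(0.9), 50, 50 + shift_for(0.9))  # .9 to gt2
  expect_equal(box_iou(det1, gt$boxes[1, ]), 0.8, tolerance = 1e-12)
  expect_equal(box_iou(det2, gt$boxes[1, ]), 0.6, tolerance = 1e-12)
  expect_equal(box_iou(det3, gt$boxes[2, ]), 0.9, tolerance = 1e-12)
  dets <- list(boxes = rbind(det1, det2, det3),
               scores = c(0.9, 0.8, 0.7), classes = c(1L, 1L, 1L))
  m <- match_detections(dets$boxes, dets$scores, dets$classes,
                        gt$boxes, gt$classes, iou_threshold = 0.5)
  expect_equal(m$tp, c(TRUE, FALSE, TRUE))
  expect_equal(average_precision(m$tp, 2L), 253 / 303)
  res <- evaluate_detections(list(dets), list(gt), num_classes = 1L)
  expect_equal(res$ap50, 253 / 303)
  # and the independent all-pairs oracle agrees
  expect_equal(oracle_ap_per_class(list(dets), list(gt), 1L, 0.5),
               253 / 303)
})

test_that("perfect and absent detections bound the metrics", {
  set.seed(51)
  gts <- lapply(1:3, function(i) {
    list(boxes = random_boxes(4, min_side = 5),
         classes = sample(1:2, 4, replace = TRUE))
  })
  perfect <- lapply(gts, function(g) {
    list(boxes = g$boxes, scores = rep(1, 4), classes = g$classes)
  })
  res <- evaluate_detections(perfect, gts, num_classes = 2L)
  expect_equal(res$ap50, 1); expect_equal(res$ap75, 1)
  expect_equal(res$ap_mean, 1); expect_equal(res$m_recall, 1)
  none <- lapply(gts, function(g) {
    list(boxes = matrix(numeric(0), 0, 4), scores = numeric(0),
         classes = integer(0))
  })
  res0 <- evaluate_detections(none, gts, num_classes = 2L)
  expect_equal(res0$ap50, 0); expect_equal(res0$m_recall, 0)
})

test_that("interpolated precision is monotone and score-scale invariant", {
  set.seed(52)
  tp <- runif(40) > 0.4
  grid <- seq(0, 1, length.out = 101)
  cum_tp <- cumsum(tp); rec <- cum_tp / 20
  prec <- cum_tp / seq_along(tp)
  interp <- vapply(grid, function(r) {
    s <- prec[rec >= r]; if (length(s)) max(s) else 0
  }, numeric(1))
  expect_true(all(diff(interp) <= 1e-12))
  sc <- random_eval_scenes(5, 53)
  r1 <- evaluate_detections(sc$dets, sc$gts, 3L, mode = "coco")
  scaled <- lapply(sc$dets, function(d) {
    d$scores <- d$scores * 0.37; d
  })
  r2 <- evaluate_detections(scaled, sc$gts, 3L, mode = "coco")
  expect_equal(r1$ap_mean, r2$ap_mean)
})

test_that("coco-mode AP agrees with the independent evaluator", {
  for (s in 1:20) {
    sc <- random_eval_scenes(3, 1000 + s)
    res <- evaluate_detections(sc$dets, sc$gts, 3L, mode = "coco")
    for (thr in c(0.5, 0.75)) {
      col <- which(abs(res$thresholds - thr) < 1e-9)
      for (k in 1:3) {
        ora <- oracle_ap_per_class(sc$dets, sc$gts, k, thr)
        if (is.na(ora)) {
          expect_true(is.na(res$per_class_ap[k, col]))
        } else {
          expect_equal(unname(res$per_class_ap[k, col]), ora, tolerance = 1e-6)
        }
      }
    }
  }
})
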