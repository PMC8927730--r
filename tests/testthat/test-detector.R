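# Anchors, assignment, sampling, proposals, losses, ablation switch.

test_that("anchor grids follow the cell-center convention", {
  m <- feature_map(array(0, c(25, 34, 4)), 32L)
  fp <- feature_pyramid(list(m))
  anch <- generate_anchors(c(800, 1088), fp, anchor_config(ratios = 1))
  expect_length(anch, 1L)
  expect_equal(nrow(anch[[1L]]), 850L)
  # first anchor sits on the first cell center (stride * 0.5)
  base <- 4 * 32
  expect_equal(anch[[1L]][1L, ],
               c(16 - base / 2, 16 - base / 2, 16 + base / 2, 16 + base / 2),
               ignore_attr = TRUE)
  # anchors are unclipped: corners may be negative
  expect_true(any(anch[[1L]] < 0))
  a3 <- generate_anchors(c(800, 1088), fp,
                         anchor_config(ratios = c(0.5, 1, 2)))
  expect_equal(nrow(a3[[1L]]), 3L * 850L)
})

test_that("assignment applies Soft-IoU thresholds and the rescue rule", {
  si <- soft_iou_config()
  sam <- sampler_config()
  gt <- matrix(c(10, 10, 30, 30), 1)
  # candidate identical to gt: SI = 0.9 >= 0.5, positive
  cands <- rbind(c(10, 10, 30, 30), c(200, 200, 220, 220))
  a <- assign_targets(cands, gt, sam, si)
  expect_equal(a$labels, c(1L, 0L))
  expect_equal(a$matched, c(1L, NA_integer_))
  # empty ground truth: everything negative
  a0 <- assign_targets(cands, matrix(numeric(0), 0, 4), sam, si)
  expect_equal(a0$labels, c(0L, 0L))
  # rescue: a gt whose best candidate is below threshold still gets one
  far <- matrix(c(12, 12, 28, 28) + 8, 1)  # IoU ~ 0.2-0.4 with gt
  a1 <- assign_targets(far, gt, sam, si)
  expect_equal(a1$labels, 1L)
  expect_equal(a1$matched, 1L)
})

test_that("Soft-IoU assignment demotes center-shifted borderline boxes", {
  # candidate with IoU 0.55 but displaced center: the Soft-IoU floor
  # 0.9 * 0.55 = 0.495 < 0.5, so SI assignment says negative while plain
  # IoU assignment says positive
  gt <- matrix(c(0, 0, 20, 11), 1)
  s <- 99 / 31  # vertical shift making IoU exactly 0.55
  cand <- matrix(c(0, s, 20, 11 + s), 1)
  iou <- box_iou(cand[1, ], gt[1, ])
  expect_equal(iou, 0.55, tolerance = 1e-10)
  si_val <- soft_iou(cand[1, ], gt[1, ], beta = 0.9, clamp_factor = 0.1)
  expect_equal(si_val, 0.9 * iou, tolerance = 1e-10)
  expect_lt(si_val, 0.5)
  # two candidates so the rescue rule goes to the better-centered one
  good <- matrix(c(0, 0.5, 20, 11.5), 1)
  cands <- rbind(cand, good)
  a_si <- assign_targets(cands, gt, sampler_config(assign_score = "soft_iou"))
  a_iou <- assign_targets(cands, gt, sampler_config(assign_score = "iou"))
  expect_equal(a_si$labels[1L], 0L)
  expect_equal(a_iou$labels[1L], 1L)
})

test_that("mini-batch sampling hits the 256-sample 1:1 protocol", {
  mk <- function(n_pos, n_neg) {
    list(labels = c(rep(1L, n_pos), rep(0L, n_neg)),
         matched = c(rep(1L, n_pos), rep(NA_integer_, n_neg)))
  }
  set.seed(31)
  s <- sample_minibatch(mk(300, 300), sampler_config())
  expect_length(s$positive, 128L)
  expect_length(s$negative, 128L)
  s2 <- sample_minibatch(mk(10, 500), sampler_config())
  expect_length(s2$positive, 10L)
  expect_length(s2$negative, 246L)
  set.seed(77); a <- sample_minibatch(mk(300, 300), sampler_config())
  set.seed(77); b <- sample_minibatch(mk(300, 300), sampler_config())
  expect_identical(a, b)
  expect_error(sample_minibatch(list(labels = integer(0)), sampler_config()),
               "no candidates")
})

test_that("proposal selection respects the cap, bounds and NMS idempotence", {
  set.seed(32)
  model <- init_detector(desk_config(num_classes = 2L, neck = "fpn"),
                         seed = 32)
  img <- array(runif(128 * 128 * 3), c(128, 128, 3))
  pyr4 <- trapdetect:::backbone_forward(model$params$backbone,
                                        model$config$backbone, img)
  lv <- trapdetect:::neck_forward_any(model$params, model$config, pyr4)
  fp <- feature_pyramid(lapply(lv, function(l) feature_map(l$x, l$stride)))
  rp <- rpn_forward(fp, model)
  anch <- generate_anchors(c(128, 128), fp, model$config$anchors)
  props <- select_proposals(rp, anch, c(128, 128), model$config$rpn)
  expect_lte(nrow(props$boxes), model$config$rpn$num_proposals)
  expect_true(all(props$boxes[, c(1, 3)] >= 0 &
                    props$boxes[, c(1, 3)] <= 128))
  expect_true(all(props$boxes[, c(2, 4)] >= 0 &
                    props$boxes[, c(2, 4)] <= 128))
  expect_equal(props$scores, sort(props$scores, decreasing = TRUE))
  # default full-scale config forwards at most 1,000 regions
  expect_equal(rpn_config()$num_proposals, 1000L)
  # NMS idempotence
  keep1 <- nms(props$boxes, props$scores, 0.7)
  keep2 <- keep1[nms(props$boxes[keep1, , drop = FALSE],
                     props$scores[keep1], 0.7)]
  expect_equal(keep2, keep1)
})

test_that("box delta encoding and decoding are mutual inverses", {
  set.seed(33)
  boxes <- random_boxes(50, min_side = 2)
  targets <- random_boxes(50, min_side = 2)
  d <- trapdetect:::encode_deltas(boxes, targets)
  back <- trapdetect:::decode_deltas(boxes, d)
  expect_equal(back, targets, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("losses are finite and decrease when overfitting one image", {
  fix <- smoke_fixture(1L)
  cfg <- desk_config(num_classes = 3L, neck = "fpn", iters = 50L)
  model <- init_detector(cfg, seed = 41)
  l0 <- compute_losses(model, fix$images[[1L]], fix$annotations[[1L]]$boxes,
                       fix$annotations[[1L]]$classes)
  expect_true(all(vapply(l0, is.finite, logical(1))))
  model <- train_detector(model, fix$images[1L], fix$annotations[1L],
                          seed = 41)
  h <- model$loss_history
  expect_lt(mean(tail(h, 10)), 0.55 * mean(head(h, 10)))
})

test_that("hard-IoU ablation reproduces plain threshold decisions exactly", {
  set.seed(34)
  gt <- random_boxes(4, extent = 120, min_side = 10)
  cands <- rbind(random_boxes(300, extent = 120, min_side = 4),
                 gt + rnorm(16, sd = 1))
  sam <- sampler_config(assign_score = "iou")
  si_off <- soft_iou_config(clamp_factor = 0)
  got <- assign_targets(cands, gt, sam, si_off)
  # independent hard-IoU oracle with the same thresholds + argmax rescue
  iou <- pairwise_iou(cands, gt)
  best <- apply(iou, 1, max)
  labels <- ifelse(best >= 0.5, 1L, 0L)
  matched <- ifelse(labels == 1L, apply(iou, 1, which.max), NA_integer_)
  for (j in seq_len(ncol(iou))) {
    if (max(iou[, j]) > 1e-8) {
      i <- which.max(iou[, j])
      labels[i] <- 1L
      if (is.na(matched[i]) || iou[i, matched[i]] < iou[i, j]) matched[i] <- j
    }
  }
  expect_identical(got$labels, labels)
  expect_identical(got$matched, matched)
})

test_that("inference returns an empty frame on a featureless image", {
  model <- init_detector(desk_config(num_classes = 2L, neck = "fpn",
                                     iters = 1L), seed = 55)
  # zero the heads: logits all zero, every class prob equal and tiny
  model$params$head$cls$w <- model$params$head$cls$w * 0
  model$params$head$cls$b <- c(-20, -20, 20)  # background wins everywhere
  d <- infer(array(0.5, c(64, 64, 3)), model, score_threshold = 0.5)
  expect_s3_class(d, "data.frame")
  expect_equal(nrow(d), 0L)
})
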