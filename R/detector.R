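# Two-stage detector: backbone -> neck -> RPN -> proposal sampling with
# Soft-IoU assignment -> RoIAlign -> classification/regression head.

#' RPN configuration
#'
#' @param num_proposals Maximum proposals forwarded to the second stage
#'   after NMS. Default 1000.
#' @param nms_threshold Plain-IoU NMS threshold among proposals.
#' @param pre_nms_per_level Top-scoring candidates kept per level before
#'   NMS.
#' @param min_size Minimum proposal side length in pixels after clipping.
#' @return An object of class "rpn_config".
#' @export
rpn_config <- function(num_proposals = 1000L, nms_threshold = 0.7,
                       pre_nms_per_level = 1000L, min_size = 1) {
  stopifnot(num_proposals > 0, pre_nms_per_level > 0)
  structure(list(num_proposals = as.integer(num_proposals),
                 nms_threshold = nms_threshold,
                 pre_nms_per_level = as.integer(pre_nms_per_level),
                 min_size = min_size),
            class = "rpn_config")
}

#' Second-stage head configuration
#' @param roi_size RoIAlign output grid side length.
#' @param fc_dim Width of the hidden fully connected layer.
#' @param finest_scale Box scale (sqrt of area) mapped to the finest
#'   pyramid level by the RoI level heuristic.
#' @return An object of class "head_config".
#' @export
head_config <- function(roi_size = 7L, fc_dim = 256L, finest_scale = 32) {
  structure(list(roi_size = as.integer(roi_size),
                 fc_dim = as.integer(fc_dim),
                 finest_scale = finest_scale),
            class = "head_config")
}

#' Training configuration
#' @param epochs Training epochs when `iters` is NULL (one image per
#'   iteration, so an epoch is one pass over the images).
#' @param momentum SGD momentum.
#' @param lr Base learning rate.
#' @param lr_decay_frac Fraction of iterations after which the rate is
#'   multiplied by `lr_decay_factor` (2/3 mirrors an 8-of-12-epoch step).
#' @param lr_decay_factor Step decay multiplier.
#' @param iters Total iterations override.
#' @param grad_clip Global gradient-norm clip.
#' @param warmup_iters Linear learning-rate warmup length (iterations);
#'   standard stabilizer for randomly initialized detector training.
#' @param add_gt_proposals Append ground-truth boxes to the second-stage
#'   proposals during training (stabilizes early training).
#' @return An object of class "training_config".
#' @export
training_config <- function(epochs = 12L, momentum = 0.9, lr = 0.0025,
                            lr_decay_frac = 2 / 3, lr_decay_factor = 0.1,
                            iters = NULL, grad_clip = 10,
                            warmup_iters = 0L,
                            add_gt_proposals = TRUE) {
  structure(list(epochs = as.integer(epochs), momentum = momentum, lr = lr,
                 lr_decay_frac = lr_decay_frac,
                 lr_decay_factor = lr_decay_factor,
                 iters = if (is.null(iters)) NULL else as.integer(iters),
                 grad_clip = grad_clip,
                 warmup_iters = as.integer(warmup_iters),
                 add_gt_proposals = isTRUE(add_gt_proposals)),
            class = "training_config")
}

#' Test-time configuration
#' @param score_threshold Minimum class score kept.
#' @param nms_threshold Duplicate-removal overlap threshold.
#' @param nms_measure Overlap measure for duplicate removal; "soft_iou"
#'   uses the test-phase beta.
#' @param max_detections Per-image cap on returned detections.
#' @return An object of class "test_config".
#' @export
test_config <- function(score_threshold = 0.05, nms_threshold = 0.5,
                        nms_measure = c("soft_iou", "iou"),
                        max_detections = 100L) {
  structure(list(score_threshold = score_threshold,
                 nms_threshold = nms_threshold,
                 nms_measure = match.arg(nms_measure),
                 max_detections = as.integer(max_detections)),
            class = "test_config")
}

#' Detector configuration
#'
#' Bundles every sub-configuration of the two-stage pipeline. The training
#' defaults follow the standard protocol for this detector family: SGD with
#' momentum 0.9, 12 epochs at learning rate 0.0025 dropped to 0.00025 for
#' the final third, 256-sample 1:1 mini-batches per image, 1,000 proposals,
#' L1 regression loss in the RPN and SmoothL1 in the second stage.
#'
#' @param num_classes Number of foreground classes K.
#' @param neck "msr", "fpn" (baseline comparison neck) or "none" (lateral
#'   projections only). Both necks emit the same 5-level stride-4..64
#'   pyramid, so they are swappable without touching anything downstream.
#' @param backbone,msr,anchors,rpn,soft_iou,head,training,test Component
#'   configurations; see the respective constructors.
#' @param sampler_rpn,sampler_rcnn [sampler_config()]s for the two
#'   assignment/sampling stages.
#' @return An object of class "detector_config".
#' @export
detector_config <- function(num_classes = 8L,
                            neck = c("msr", "fpn", "none"),
                            backbone = backbone_config(),
                            msr = msr_config(),
                            anchors = anchor_config(),
                            sampler_rpn = sampler_config(),
                            sampler_rcnn = sampler_config(),
                            rpn = rpn_config(),
                            soft_iou = soft_iou_config(),
                            head = head_config(),
                            training = training_config(),
                            test = test_config()) {
  structure(list(num_classes = as.integer(num_classes),
                 neck = match.arg(neck), backbone = backbone, msr = msr,
                 anchors = anchors, sampler_rpn = sampler_rpn,
                 sampler_rcnn = sampler_rcnn, rpn = rpn,
                 soft_iou = soft_iou, head = head, training = training,
                 test = test),
            class = "detector_config")
}

#' A small desk-scale detector configuration
#'
#' A complete configuration sized for CPU experiments and the test suite:
#' narrow backbone (8, 16, 32, 64 channels), 32-channel neck, small head,
#' short proposal lists. The pipeline is identical to the full-size
#' default; only widths and list lengths shrink.
#'
#' @param num_classes Number of foreground classes.
#' @param neck Neck type, as in [detector_config()].
#' @param iters Total training iterations.
#' @param lr Learning rate (higher than the full-scale default because the
#'   network is tiny and the schedule short).
#' @return A [detector_config()].
#' @export
desk_config <- function(num_classes = 3L, neck = "msr", iters = 200L,
                        lr = 0.015) {
  detector_config(
    num_classes = num_classes, neck = neck,
    backbone = backbone_config(stage_channels = c(8L, 16L, 32L, 64L),
                               stem_channels = 8L),
    msr = msr_config(out_channels = 32L),
    anchors = anchor_config(ratios = c(0.5, 1, 2), scale = 2),
    rpn = rpn_config(num_proposals = 300L, pre_nms_per_level = 300L),
    head = head_config(roi_size = 7L, fc_dim = 128L),
    training = training_config(iters = iters, lr = lr,
                               warmup_iters = min(30L, iters %/% 4L)),
    test = test_config(max_detections = 50L))
}

#' Initialize detector parameters
#'
#' Backbone and neck use He-style initialization; the classification and
#' regression output layers use zero-mean Gaussians with SD 0.01.
#'
#' @param config A [detector_config()].
#' @param seed Optional integer seed for reproducible initialization.
#' @return An object of class "trap_detector" (untrained).
#' @export
init_detector <- function(config = detector_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  C <- config$msr$out_channels
  A <- length(config$anchors$ratios)
  in_ch <- config$backbone$stage_channels
  neck <- switch(config$neck,
    msr = init_msr_neck(config$msr, in_ch)$params,
    fpn = init_fpn_neck(config$msr, in_ch)$params,
    none = list(lateral = lapply(in_ch, function(ci)
      init_conv(1L, 1L, ci, C))))
  D <- C * config$head$roi_size^2
  params <- list(
    backbone = init_backbone(config$backbone),
    neck = neck,
    rpn = list(conv = init_conv(3L, 3L, C, C),
               cls = init_conv(1L, 1L, C, A, sd = 0.01),
               reg = init_conv(1L, 1L, C, 4L * A, sd = 0.01)),
    head = list(
      fc1 = list(w = matrix(stats::rnorm(D * config$head$fc_dim,
                                         sd = sqrt(2 / D)),
                            D, config$head$fc_dim),
                 b = numeric(config$head$fc_dim)),
      cls = list(w = matrix(stats::rnorm(config$head$fc_dim *
                                           (config$num_classes + 1L),
                                         sd = 0.01),
                            config$head$fc_dim, config$num_classes + 1L),
                 b = numeric(config$num_classes + 1L)),
      reg = list(w = matrix(stats::rnorm(config$head$fc_dim * 4L, sd = 0.01),
                            config$head$fc_dim, 4L),
                 b = numeric(4L)))
  )
  structure(list(params = params, config = config,
                 loss_history = numeric(0), trained_iters = 0L),
            class = "trap_detector")
}

#' @export
print.trap_detector <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Two-stage pest detector\n  neck: %s (%d channels), classes: %d\n",
    cfg$neck, cfg$msr$out_channels, cfg$num_classes))
  cat(sprintf("  trained iterations: %d", x$trained_iters))
  if (length(x$loss_history)) {
    cat(sprintf(", final loss %.4f", tail(x$loss_history, 1L)))
  }
  cat("\n")
  invisible(x)
}

# ---- forward helpers (arrays or ad nodes) ---------------------------------

neck_forward_any <- function(params, config, pyr4) {
  switch(config$neck,
    msr = msr_forward_core(params$neck, config$msr, pyr4),
    fpn = fpn_forward_core(params$neck, config$msr, pyr4),
    none = {
      lat <- lapply(1:4, function(i) {
        list(x = ad_conv2d(pyr4[[i]]$x, params$neck$lateral[[i]]$w,
                           params$neck$lateral[[i]]$b,
                           stride = 1L, pad = 0L),
             stride = pyr4[[i]]$stride)
      })
      c(lat, list(list(x = ad_subsample2(lat[[4L]]$x), stride = 64L)))
    })
}

rpn_head_any <- function(params, levels) {
  lapply(levels, function(l) {
    t <- ad_relu(ad_conv2d(l$x, params$rpn$conv$w, params$rpn$conv$b,
                           stride = 1L, pad = 1L))
    list(cls = ad_conv2d(t, params$rpn$cls$w, params$rpn$cls$b,
                         stride = 1L, pad = 0L),
         reg = ad_conv2d(t, params$rpn$reg$w, params$rpn$reg$b,
                         stride = 1L, pad = 0L),
         stride = l$stride)
  })
}

#' RPN forward pass
#'
#' @param pyramid 5-level [feature_pyramid()] from the neck.
#' @param model A [init_detector()] / trained "trap_detector" object.
#' @return Per level: objectness logits (H x W x A) and box deltas
#'   (H x W x 4A).
#' @export
rpn_forward <- function(pyramid, model) {
  levels <- fp_to_internal(pyramid)
  out <- rpn_head_any(model$params, levels)
  lapply(out, function(o) list(cls = ad_value(o$cls),
                               reg = ad_value(o$reg),
                               stride = o$stride))
}

# Index vector mapping an (H, W, 4A) delta map (column-major) onto an
# (N, 4) matrix with rows ordered (row fastest, col, anchor) — the anchor
# order of anchors_for_level().
delta_index <- function(H, W, A) {
  HW <- H * W
  p <- rep(seq_len(HW) - 1L, times = A)
  a <- rep(seq_len(A) - 1L, each = HW)
  idx <- matrix(0L, HW * A, 4L)
  for (d in 1:4) idx[, d] <- p + (a * 4L + d - 1L) * HW + 1L
  as.vector(idx)
}

level_deltas_any <- function(reg, A) {
  d <- dim(ad_value(reg))
  N <- d[1L] * d[2L] * A
  ad_reshape(ad_gather(reg, delta_index(d[1L], d[2L], A)), c(N, 4L))
}

#' Select proposals from RPN outputs
#'
#' Per level: take the top-scoring candidates, decode their box deltas
#' against the anchors, clip to the image, drop degenerate boxes and run
#' plain-IoU NMS; then merge levels, sort by objectness and keep at most
#' `num_proposals`.
#'
#' @param rpn_out Output of [rpn_forward()].
#' @param anchors Per-level anchor matrices from [generate_anchors()].
#' @param image_size c(height, width).
#' @param config An [rpn_config()].
#' @return List with `boxes` (n x 4) and `scores` (objectness in (0, 1)),
#'   sorted by decreasing score, n <= num_proposals.
#' @export
select_proposals <- function(rpn_out, anchors, image_size,
                             config = rpn_config()) {
  all_boxes <- list(); all_scores <- list()
  for (l in seq_along(rpn_out)) {
    cls <- ad_value(rpn_out[[l]]$cls)
    reg <- ad_value(rpn_out[[l]]$reg)
    A <- dim(cls)[3L]
    scores <- 1 / (1 + exp(-as.vector(cls)))
    deltas <- ad_value(level_deltas_any(reg, A))
    anc <- anchors[[l]]
    keep_n <- min(length(scores), config$pre_nms_per_level)
    ord <- order(scores, decreasing = TRUE)[seq_len(keep_n)]
    boxes <- decode_deltas(anc[ord, , drop = FALSE],
                           deltas[ord, , drop = FALSE])
    boxes <- clip_boxes(boxes, image_size)
    sc <- scores[ord]
    ok <- (boxes[, 3L] - boxes[, 1L]) >= config$min_size &
      (boxes[, 4L] - boxes[, 2L]) >= config$min_size
    boxes <- boxes[ok, , drop = FALSE]; sc <- sc[ok]
    if (nrow(boxes) == 0L) next
    keep <- nms(boxes, sc, threshold = config$nms_threshold,
                measure = "iou")
    all_boxes[[l]] <- boxes[keep, , drop = FALSE]
    all_scores[[l]] <- sc[keep]
  }
  if (length(all_boxes) == 0L) {
    return(list(boxes = matrix(numeric(0), 0L, 4L), scores = numeric(0)))
  }
  boxes <- do.call(rbind, all_boxes)
  scores <- unlist(all_scores)
  ord <- order(scores, decreasing = TRUE)
  ord <- ord[seq_len(min(length(ord), config$num_proposals))]
  list(boxes = boxes[ord, , drop = FALSE], scores = scores[ord])
}

# Map each box to a pyramid level by the size heuristic:
# level = clamp(floor(log2(sqrt(area) / finest_scale)), 0, L-1) + 1.
roi_levels <- function(boxes, n_levels = 5L, finest_scale = 32) {
  scale <- sqrt(pmax(box_area(boxes), 1e-6))
  k <- floor(log2(scale / finest_scale + 1e-6))
  pmin(pmax(k, 0), n_levels - 1L) + 1L
}

# RoIAlign over a pyramid (arrays or nodes). Returns feats (n x D, rows in
# `perm` order) and the permutation of input box indices.
roi_feats_any <- function(levels, boxes, out_size, finest_scale) {
  lv <- roi_levels(boxes, length(levels), finest_scale)
  feats <- list(); perm <- list()
  for (l in sort(unique(lv))) {
    sel <- which(lv == l)
    stride <- levels[[l]]$stride
    rois <- boxes[sel, , drop = FALSE] / stride - 0.5
    g <- ad_roi_align(levels[[l]]$x, rois, out_size)
    C <- dim(ad_value(levels[[l]]$x))[3L]
    D <- out_size * out_size * C
    feats[[length(feats) + 1L]] <-
      ad_transpose(ad_reshape(g, c(D, length(sel))))
    perm[[length(perm) + 1L]] <- sel
  }
  list(feats = ad_rbind(feats), perm = unlist(perm))
}

#' RoIAlign pooling over a feature pyramid
#'
#' Bilinear, alignment-preserving pooling of each box's features to a
#' fixed square grid, the level chosen by the standard size heuristic.
#'
#' @param pyramid 5-level [feature_pyramid()].
#' @param boxes n x 4 box matrix in image coordinates.
#' @param output_size Side length of the pooled grid.
#' @param finest_scale Box scale (sqrt area) mapped to the finest level.
#' @return Array (output_size, output_size, C, n), boxes in input order.
#' @export
roi_pool <- function(pyramid, boxes, output_size = 7L, finest_scale = 32) {
  boxes <- as_box_matrix(boxes)
  levels <- fp_to_internal(pyramid)
  out_size <- as.integer(output_size)
  C <- dim(ad_value(levels[[1L]]$x))[3L]
  res <- array(0, c(out_size, out_size, C, nrow(boxes)))
  lv <- roi_levels(boxes, length(levels), finest_scale)
  for (l in sort(unique(lv))) {
    sel <- which(lv == l)
    stride <- levels[[l]]$stride
    rois <- boxes[sel, , drop = FALSE] / stride - 0.5
    res[, , , sel] <- .cpp_roi_align_fwd(ad_value(levels[[l]]$x), rois,
                                         out_size)
  }
  res
}

head_forward_any <- function(params, feats) {
  h <- ad_relu(ad_linear(feats, params$head$fc1$w, params$head$fc1$b))
  list(cls = ad_linear(h, params$head$cls$w, params$head$cls$b),
       reg = ad_linear(h, params$head$reg$w, params$head$reg$b))
}

softmax_rows <- function(m) {
  e <- exp(m - apply(m, 1L, max))
  e / rowSums(e)
}
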