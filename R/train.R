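# Training: per-image loss assembly, SGD with momentum, schedules.

# Wrap every double-typed leaf of a nested parameter list in an ad_var
# node (integers and other metadata pass through untouched).
wrap_params <- function(p) {
  if (is.list(p)) {
    at <- attributes(p)
    out <- lapply(p, wrap_params)
    attributes(out) <- at
    return(out)
  }
  if (is.double(p)) return(ad_var(p))
  p
}

# Collect gradients from a wrapped parameter tree, zeros where untouched.
collect_grads <- function(pn) {
  if (is.list(pn)) return(lapply(pn, collect_grads))
  if (is_ad_node(pn)) {
    g <- pn$grad
    if (is.null(g)) {
      g <- pn$value * 0
    }
    return(g)
  }
  NULL
}

grad_sqnorm <- function(g) {
  if (is.list(g)) return(sum(vapply(g, grad_sqnorm, numeric(1))))
  if (is.null(g)) return(0)
  sum(g^2)
}

zero_like <- function(p) {
  if (is.list(p)) return(lapply(p, zero_like))
  if (is.double(p)) return(p * 0)
  NULL
}

sgd_step <- function(params, grads, vel, lr, momentum, scale) {
  if (is.list(params)) {
    at <- attributes(params)
    out_p <- params; out_v <- vel
    for (k in seq_along(params)) {
      r <- sgd_step(params[[k]], grads[[k]], vel[[k]], lr, momentum, scale)
      out_p[[k]] <- r$p; out_v[[k]] <- r$v
    }
    attributes(out_p) <- at
    return(list(p = out_p, v = out_v))
  }
  if (!is.double(params)) return(list(p = params, v = vel))
  v <- momentum * vel + grads * scale
  list(p = params - lr * v, v = v)
}

# Per-image losses; `params` may be wrapped (training) or plain arrays.
detector_losses <- function(params, config, image, gt_boxes, gt_classes) {
  pyr4 <- backbone_forward(params$backbone, config$backbone, image)
  levels <- neck_forward_any(params, config, pyr4)
  rpn_out <- rpn_head_any(params, levels)
  image_size <- dim(ad_value(image))[1:2]
  fp <- feature_pyramid(lapply(levels, function(l) {
    feature_map(ad_value(l$x) * 0, l$stride)  # sizes only
  }))
  anchors <- generate_anchors(image_size, fp, config$anchors)
  A <- length(config$anchors$ratios)

  obj_logits <- ad_rbind(lapply(rpn_out, function(o) {
    d <- dim(ad_value(o$cls))
    ad_reshape(o$cls, c(prod(d), 1L))
  }))
  deltas <- ad_rbind(lapply(rpn_out, function(o) {
    level_deltas_any(o$reg, A)
  }))
  all_anchors <- do.call(rbind, anchors)

  assign_rpn <- assign_targets(all_anchors, gt_boxes, config$sampler_rpn,
                               config$soft_iou)
  samp <- sample_minibatch(assign_rpn, config$sampler_rpn)
  sel <- c(samp$positive, samp$negative)
  n_samp <- length(sel)
  rpn_cls <- ad_sigmoid_bce(
    ad_rows(obj_logits, sel),
    c(rep(1, length(samp$positive)), rep(0, length(samp$negative))))
  rpn_reg <- if (length(samp$positive) > 0L) {
    tgt <- encode_deltas(
      all_anchors[samp$positive, , drop = FALSE],
      gt_boxes[assign_rpn$matched[samp$positive], , drop = FALSE])
    # per-coordinate mean over positives: keeps the localization gradient
    # strong when positives are scarce
    ad_l1_loss(ad_rows(deltas, samp$positive), tgt,
               norm = 4L * length(samp$positive))
  } else 0

  proposals <- select_proposals(
    lapply(rpn_out, function(o) list(cls = ad_value(o$cls),
                                     reg = ad_value(o$reg))),
    anchors, image_size, config$rpn)$boxes
  if (config$training$add_gt_proposals && NROW(gt_boxes) > 0L) {
    # ground truth plus jittered copies: gives the head well-overlapping
    # but imperfect boxes to regress from, matching what it sees at test
    # time
    gw <- gt_boxes[, 3L] - gt_boxes[, 1L]
    gh <- gt_boxes[, 4L] - gt_boxes[, 2L]
    jitter_one <- function() {
      j <- gt_boxes +
        cbind(gw * stats::rnorm(length(gw), sd = 0.12),
              gh * stats::rnorm(length(gh), sd = 0.12),
              gw * stats::rnorm(length(gw), sd = 0.12),
              gh * stats::rnorm(length(gh), sd = 0.12))
      j[, 3L] <- pmax(j[, 3L], j[, 1L] + 1)
      j[, 4L] <- pmax(j[, 4L], j[, 2L] + 1)
      clip_boxes(j, image_size)
    }
    proposals <- rbind(proposals, gt_boxes, jitter_one(), jitter_one())
  }
  if (nrow(proposals) == 0L) {
    stop("no proposals produced; cannot train on this image")
  }
  assign_rcnn <- assign_targets(proposals, gt_boxes, config$sampler_rcnn,
                                config$soft_iou)
  samp2 <- sample_minibatch(assign_rcnn, config$sampler_rcnn)
  sel2 <- c(samp2$positive, samp2$negative)
  labels <- c(gt_classes[assign_rcnn$matched[samp2$positive]],
              rep(config$num_classes + 1L, length(samp2$negative)))
  rois <- proposals[sel2, , drop = FALSE]
  rf <- roi_feats_any(levels, rois, config$head$roi_size,
                      config$head$finest_scale)
  labels_p <- labels[rf$perm]  # feats row r holds roi rf$perm[r]
  head_out <- head_forward_any(params, rf$feats)
  rcnn_cls <- ad_softmax_ce(head_out$cls, labels_p)
  pos_in_perm <- which(rf$perm <= length(samp2$positive))
  rcnn_reg <- if (length(pos_in_perm) > 0L) {
    orig_pos <- rf$perm[pos_in_perm]  # indices into sel2 (all positives)
    prop_pos <- rois[orig_pos, , drop = FALSE]
    gt_pos <- gt_boxes[assign_rcnn$matched[sel2[orig_pos]], , drop = FALSE]
    tgt <- encode_deltas(prop_pos, gt_pos)
    ad_smooth_l1_loss(ad_rows(head_out$reg, pos_in_perm), tgt,
                      beta = 1, norm = 4L * length(pos_in_perm))
  } else 0

  total <- ad_sum_scalars(list(rpn_cls, rpn_reg, rcnn_cls, rcnn_reg))
  list(total = total, rpn_cls = ad_value(rpn_cls),
       rpn_reg = ad_value(rpn_reg), rcnn_cls = ad_value(rcnn_cls),
       rcnn_reg = ad_value(rcnn_reg))
}

#' Compute the four detector losses on one image
#'
#' Runs the full training-time pipeline (assignment with the configured
#' score, 1:1 sampling, RoIAlign, heads) and returns the loss components:
#' binary cross-entropy RPN objectness, L1 RPN box regression, softmax
#' cross-entropy for the second-stage classifier and SmoothL1 for its box
#' regression.
#'
#' @param model A "trap_detector".
#' @param image H x W x 3 array.
#' @param gt_boxes m x 4 ground-truth boxes.
#' @param gt_classes Integer classes in 1..K.
#' @return Named list of scalar losses (rpn_cls, rpn_reg, rcnn_cls,
#'   rcnn_reg, total), all finite.
#' @export
compute_losses <- function(model, image, gt_boxes, gt_classes) {
  l <- detector_losses(model$params, model$config, image,
                       gt_boxes, gt_classes)
  out <- list(rpn_cls = l$rpn_cls, rpn_reg = l$rpn_reg,
              rcnn_cls = l$rcnn_cls, rcnn_reg = l$rcnn_reg,
              total = ad_value(l$total))
  if (!all(vapply(out, is.finite, logical(1)))) {
    stop("non-finite loss: ", paste(names(out), unlist(out),
                                    collapse = ", "))
  }
  out
}

#' Train the detector with SGD
#'
#' One image per iteration, cycled in order; the learning rate drops by
#' `lr_decay_factor` after `lr_decay_frac` of the iterations (mirroring an
#' 8-of-12-epoch step schedule). Gradients are clipped to a global norm.
#' All randomness (sampling, initialization if the model is fresh) is
#' governed by `seed`.
#'
#' @param model A "trap_detector" from [init_detector()].
#' @param images List of H x W x 3 arrays.
#' @param annotations List (same length) of list(boxes = m x 4 matrix,
#'   classes = integer vector in 1..K).
#' @param seed Integer seed.
#' @param verbose Print running loss every 20 iterations.
#' @return The trained "trap_detector" (params updated, loss history
#'   appended).
#' @export
train_detector <- function(model, images, annotations, seed = 1L,
                           verbose = FALSE) {
  stopifnot(inherits(model, "trap_detector"),
            length(images) == length(annotations))
  config <- model$config
  tr <- config$training
  n_img <- length(images)
  iters <- tr$iters %||% (tr$epochs * n_img)
  set.seed(seed)
  params <- model$params
  vel <- zero_like(params)
  losses <- numeric(iters)
  decay_at <- ceiling(tr$lr_decay_frac * iters)
  for (it in seq_len(iters)) {
    i <- ((it - 1L) %% n_img) + 1L
    lr <- if (it > decay_at) tr$lr * tr$lr_decay_factor else tr$lr
    if (tr$warmup_iters > 0L && it <= tr$warmup_iters) {
      lr <- lr * it / tr$warmup_iters
    }
    ann <- annotations[[i]]
    res <- with_tape({
      pn <- wrap_params(params)
      l <- detector_losses(pn, config, images[[i]], ann$boxes, ann$classes)
      if (!is.finite(ad_value(l$total))) {
        stop(sprintf(
          "training aborted at iteration %d: non-finite loss (rpn_cls %.3g, rpn_reg %.3g, rcnn_cls %.3g, rcnn_reg %.3g)",
          it, l$rpn_cls, l$rpn_reg, l$rcnn_cls, l$rcnn_reg))
      }
      ad_backward(l$total)
      list(loss = ad_value(l$total), grads = collect_grads(pn))
    })
    losses[it] <- res$loss
    gn <- sqrt(grad_sqnorm(res$grads))
    scale <- if (is.finite(tr$grad_clip) && gn > tr$grad_clip) {
      tr$grad_clip / gn
    } else 1
    st <- sgd_step(params, res$grads, vel, lr, tr$momentum, scale)
    params <- st$p; vel <- st$v
    if (config$msr$alpha_learnable && !is.null(params$neck$alpha)) {
      params$neck$alpha <- min(max(params$neck$alpha, 0), 1)
    }
    if (verbose && it %% 20L == 0L) {
      message(sprintf("iter %d/%d  loss %.4f  lr %.4g", it, iters,
                      mean(losses[max(1L, it - 19L):it]), lr))
    }
  }
  model$params <- params
  model$loss_history <- c(model$loss_history, losses)
  model$trained_iters <- model$trained_iters + iters
  model
}

#' Run inference on one image
#'
#' Forward pass, proposal selection, second-stage scoring, then per-class
#' duplicate removal where the overlap measure is the Soft-IoU with the
#' test-phase beta (position-tolerant retention) unless configured to
#' plain IoU.
#'
#' @param image H x W x 3 array in [0, 1].
#' @param model A trained "trap_detector".
#' @param score_threshold Minimum class score kept (default from the
#'   model's test config).
#' @return data.frame with columns x1, y1, x2, y2, class_id, score, sorted
#'   by decreasing score; zero rows when nothing clears the threshold.
#' @export
infer <- function(image, model, score_threshold = NULL) {
  config <- model$config
  tc <- config$test
  if (is.null(score_threshold)) score_threshold <- tc$score_threshold
  params <- model$params
  pyr4 <- backbone_forward(params$backbone, config$backbone, image)
  levels <- neck_forward_any(params, config, pyr4)
  rpn_out <- rpn_head_any(params, levels)
  image_size <- dim(image)[1:2]
  fp <- feature_pyramid(lapply(levels, function(l) {
    feature_map(ad_value(l$x), l$stride)
  }))
  anchors <- generate_anchors(image_size, fp, config$anchors)
  props <- select_proposals(rpn_out, anchors, image_size, config$rpn)
  empty <- data.frame(x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                      y2 = numeric(0), class_id = integer(0),
                      score = numeric(0))
  if (nrow(props$boxes) == 0L) return(empty)
  rf <- roi_feats_any(levels, props$boxes, config$head$roi_size,
                      config$head$finest_scale)
  head_out <- head_forward_any(params, rf$feats)
  probs <- softmax_rows(ad_value(head_out$cls))
  reg <- ad_value(head_out$reg)
  boxes_perm <- props$boxes[rf$perm, , drop = FALSE]
  decoded <- clip_boxes(decode_deltas(boxes_perm, reg), image_size)
  ok <- (decoded[, 3L] - decoded[, 1L]) > 1e-3 &
    (decoded[, 4L] - decoded[, 2L]) > 1e-3
  out <- list()
  for (k in seq_len(config$num_classes)) {
    sel <- which(ok & probs[, k] >= score_threshold)
    if (length(sel) == 0L) next
    b <- decoded[sel, , drop = FALSE]
    s <- probs[sel, k]
    keep <- nms(b, s, threshold = tc$nms_threshold,
                measure = tc$nms_measure,
                beta = config$soft_iou$beta_test,
                clamp_factor = config$soft_iou$clamp_factor)
    out[[length(out) + 1L]] <- data.frame(
      x1 = b[keep, 1L], y1 = b[keep, 2L], x2 = b[keep, 3L],
      y2 = b[keep, 4L], class_id = k, score = s[keep])
  }
  if (length(out) == 0L) return(empty)
  dets <- do.call(rbind, out)
  dets <- dets[order(dets$score, decreasing = TRUE), , drop = FALSE]
  dets <- utils::head(dets, tc$max_detections)
  rownames(dets) <- NULL
  dets
}

#' Save / load a detector checkpoint
#'
#' Single-file serialized weights plus configuration, with a format
#' version key.
#' @param model A "trap_detector".
#' @param path Destination file.
#' @return `path`, invisibly; `load_checkpoint()` returns the model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "trap_detector"))
  saveRDS(list(format = "trapdetect-checkpoint-v1", model = model), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "trapdetect-checkpoint-v1")) {
    stop("not a trapdetect checkpoint: ", path)
  }
  obj$model
}
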