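# Anchor generation, box-delta parameterization, target assignment and
# mini-batch sampling for the two-stage detector.

#' Anchor configuration
#'
#' One anchor set per pyramid level. The base size at a level is
#' scale * stride, so anchors grow with the pyramid; aspect ratios are
#' height/width.
#'
#' @param ratios Aspect ratios (h/w) per cell. Default 1 (square anchors).
#' @param scale Base anchor size in units of the level stride. Default 4.
#' @return An object of class "anchor_config".
#' @export
anchor_config <- function(ratios = 1, scale = 4) {
  stopifnot(all(ratios > 0), scale > 0)
  structure(list(ratios = as.numeric(ratios), scale = as.numeric(scale)),
            class = "anchor_config")
}

# Anchors for one level, ordered to match the column-major flattening of
# an (H, W, A) head output: row index varies fastest, then column, then
# anchor/ratio. Centers at stride * (cell + 0.5), unclipped.
anchors_for_level <- function(hw, stride, config) {
  H <- hw[1L]; W <- hw[2L]
  cy <- rep(stride * (seq_len(H) - 0.5), times = W)
  cx <- rep(stride * (seq_len(W) - 0.5), each = H)
  base <- config$scale * stride
  out <- vector("list", length(config$ratios))
  for (a in seq_along(config$ratios)) {
    r <- config$ratios[a]
    w <- base / sqrt(r)
    h <- base * sqrt(r)
    out[[a]] <- cbind(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
  }
  do.call(rbind, out)
}

#' Generate anchors for a feature pyramid
#'
#' @param image_size c(height, width) of the source image.
#' @param pyramid A [feature_pyramid()] (its level sizes and strides drive
#'   the anchor grids).
#' @param config An [anchor_config()].
#' @return List (one entry per level) of n x 4 anchor box matrices in image
#'   coordinates, centered on cell centers at stride * (cell + 0.5),
#'   unclipped (clipping to the image is a separate, later step).
#' @export
generate_anchors <- function(image_size, pyramid, config = anchor_config()) {
  lapply(pyramid, function(l) {
    anchors_for_level(dim(l)[1:2], attr(l, "stride"), config)
  })
}

# Standard (dx, dy, dw, dh) log-space box regression parameterization.
encode_deltas <- function(boxes, targets) {
  bw <- boxes[, 3L] - boxes[, 1L]; bh <- boxes[, 4L] - boxes[, 2L]
  bx <- boxes[, 1L] + bw / 2; by <- boxes[, 2L] + bh / 2
  tw <- targets[, 3L] - targets[, 1L]; th <- targets[, 4L] - targets[, 2L]
  tx <- targets[, 1L] + tw / 2; ty <- targets[, 2L] + th / 2
  cbind((tx - bx) / bw, (ty - by) / bh, log(tw / bw), log(th / bh))
}

decode_deltas <- function(boxes, deltas, max_ratio = log(1000 / 16)) {
  bw <- boxes[, 3L] - boxes[, 1L]; bh <- boxes[, 4L] - boxes[, 2L]
  bx <- boxes[, 1L] + bw / 2; by <- boxes[, 2L] + bh / 2
  dw <- pmin(pmax(deltas[, 3L], -max_ratio), max_ratio)
  dh <- pmin(pmax(deltas[, 4L], -max_ratio), max_ratio)
  cx <- bx + deltas[, 1L] * bw
  cy <- by + deltas[, 2L] * bh
  w <- bw * exp(dw)
  h <- bh * exp(dh)
  cbind(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
}

#' Sampler configuration
#'
#' @param samples_per_image Mini-batch size drawn from one image's
#'   candidates. Default 256.
#' @param positive_fraction Target fraction of positives, in (0, 1).
#'   Default 0.5 (a 1:1 positive:negative ratio).
#' @param assign_score "soft_iou" scores candidates against ground truth
#'   with the training-phase Soft-IoU; "iou" is the hard-IoU ablation
#'   baseline.
#' @param positive_threshold,negative_threshold Score thresholds for the
#'   positive / negative decision (candidates in between are ignored).
#' @return An object of class "sampler_config".
#' @export
sampler_config <- function(samples_per_image = 256L,
                           positive_fraction = 0.5,
                           assign_score = c("soft_iou", "iou"),
                           positive_threshold = 0.5,
                           negative_threshold = 0.5) {
  stopifnot(samples_per_image > 0,
            positive_fraction > 0, positive_fraction < 1,
            positive_threshold >= 0, positive_threshold <= 1.1,
            negative_threshold >= 0, negative_threshold <= 1.1)
  structure(list(samples_per_image = as.integer(samples_per_image),
                 positive_fraction = positive_fraction,
                 assign_score = match.arg(assign_score),
                 positive_threshold = positive_threshold,
                 negative_threshold = negative_threshold),
            class = "sampler_config")
}

#' Assign candidates to ground-truth boxes
#'
#' Scores every candidate against every ground-truth box (training-phase
#' Soft-IoU by default, plain IoU under the ablation switch). A candidate
#' is positive when its best score reaches the positive threshold, or when
#' it is the best-scoring candidate for some ground-truth box (the rescue
#' rule guaranteeing every ground truth at least one positive, provided it
#' overlaps anything at all). Candidates below the negative threshold are
#' negative; anything in between is ignored. Ties go to the lowest
#' ground-truth index.
#'
#' @param candidates n x 4 box matrix (anchors or proposals).
#' @param gt_boxes m x 4 ground-truth box matrix (may have zero rows:
#'   everything becomes negative).
#' @param sampler A [sampler_config()].
#' @param si_config A [soft_iou_config()].
#' @return List with `labels` (integer vector: 1 positive, 0 negative,
#'   -1 ignore) and `matched` (ground-truth index for positives, NA
#'   otherwise).
#' @export
assign_targets <- function(candidates, gt_boxes,
                           sampler = sampler_config(),
                           si_config = soft_iou_config()) {
  candidates <- as_box_matrix(candidates)
  n <- nrow(candidates)
  labels <- integer(n)
  matched <- rep(NA_integer_, n)
  if (is.null(gt_boxes) || NROW(gt_boxes) == 0L) {
    return(list(labels = labels, matched = matched))
  }
  gt_boxes <- as_box_matrix(gt_boxes)
  score <- if (sampler$assign_score == "soft_iou") {
    pairwise_soft_iou(candidates, gt_boxes,
                      beta = si_config$beta_train,
                      clamp_factor = si_config$clamp_factor)
  } else {
    pairwise_iou(candidates, gt_boxes)
  }
  best <- apply(score, 1L, max)
  best_gt <- apply(score, 1L, which.max)  # ties: lowest gt index
  labels[best < sampler$negative_threshold] <- 0L
  labels[best >= sampler$negative_threshold &
           best < sampler$positive_threshold] <- -1L
  pos <- best >= sampler$positive_threshold
  labels[pos] <- 1L
  matched[pos] <- best_gt[pos]
  # rescue: each gt's argmax candidate becomes positive (if any overlap)
  for (j in seq_len(ncol(score))) {
    cmax <- max(score[, j])
    if (cmax > 1e-8) {
      i <- which.max(score[, j])
      labels[i] <- 1L
      if (is.na(matched[i]) || score[i, matched[i]] < score[i, j]) {
        matched[i] <- j
      }
    }
  }
  list(labels = labels, matched = matched)
}

safe_sample <- function(x, k) x[sample.int(length(x), k)]

#' Sample a training mini-batch from assigned candidates
#'
#' Draws up to samples_per_image candidates targeting the configured
#' positive fraction (1:1 by default). Scarce positives are compensated by
#' extra negatives; selection is random under the current RNG state, so a
#' fixed seed reproduces it exactly.
#'
#' @param assignment Result of [assign_targets()].
#' @param sampler A [sampler_config()].
#' @return List with integer index vectors `positive` and `negative`.
#' @export
sample_minibatch <- function(assignment, sampler = sampler_config()) {
  labels <- assignment$labels
  if (length(labels) == 0L) stop("no candidates to sample from")
  pos_idx <- which(labels == 1L)
  neg_idx <- which(labels == 0L)
  n_pos_target <- round(sampler$samples_per_image * sampler$positive_fraction)
  n_pos <- min(length(pos_idx), n_pos_target)
  pos <- if (n_pos > 0L) safe_sample(pos_idx, n_pos) else integer(0)
  n_neg <- min(length(neg_idx), sampler$samples_per_image - n_pos)
  neg <- if (n_neg > 0L) safe_sample(neg_idx, n_neg) else integer(0)
  list(positive = pos, negative = neg)
}
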