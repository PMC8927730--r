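# Detection metrics: per-class AP at fixed IoU thresholds, AP50/AP75,
# mean AP, and mean per-class recall.

#' Match detections to ground truth on one image
#'
#' Greedy one-to-one matching, highest score first, same class only: each
#' detection takes the best still-unmatched ground-truth box of its class
#' whose overlap reaches the threshold. The overlap measure is plain IoU
#' by default; "soft_iou" (test-phase beta) makes matching position-
#' tolerant.
#'
#' @param det_boxes n x 4 matrix; `det_scores`, `det_classes` length n.
#' @param gt_boxes m x 4 matrix; `gt_classes` length m.
#' @param iou_threshold Matching threshold.
#' @param measure "iou" or "soft_iou".
#' @param si_config A [soft_iou_config()] (used for "soft_iou").
#' @return List: `tp` logical vector in the order of the score-sorted
#'   detections, `order` the sort permutation, `matched_gt` ground-truth
#'   index per sorted detection (NA for false positives).
#' @export
match_detections <- function(det_boxes, det_scores, det_classes,
                             gt_boxes, gt_classes, iou_threshold = 0.5,
                             measure = c("iou", "soft_iou"),
                             si_config = soft_iou_config()) {
  measure <- match.arg(measure)
  n <- NROW(det_boxes)
  ord <- order(det_scores, decreasing = TRUE)
  tp <- logical(n)
  matched_gt <- rep(NA_integer_, n)
  m <- NROW(gt_boxes)
  if (n == 0L) return(list(tp = tp, order = ord, matched_gt = matched_gt))
  if (m > 0L) {
    ov <- if (measure == "iou") {
      pairwise_iou(det_boxes, gt_boxes)
    } else {
      pairwise_soft_iou(det_boxes, gt_boxes, beta = si_config$beta_test,
                        clamp_factor = si_config$clamp_factor)
    }
    gt_taken <- logical(m)
    for (r in seq_len(n)) {
      i <- ord[r]
      cand <- which(gt_classes == det_classes[i] & !gt_taken)
      if (length(cand) == 0L) next
      j <- cand[which.max(ov[i, cand])]
      if (ov[i, j] >= iou_threshold) {
        tp[r] <- TRUE
        matched_gt[r] <- j
        gt_taken[j] <- TRUE
      }
    }
  }
  list(tp = tp, order = ord, matched_gt = matched_gt)
}

#' 101-point interpolated average precision
#'
#' Precision is interpolated to be non-increasing (at each of 101 evenly
#' spaced recall points, the maximum precision at that recall or higher)
#' and averaged.
#'
#' @param tp Logical TP/FP flags of the detections, sorted by decreasing
#'   score.
#' @param num_gt Number of ground-truth instances.
#' @return Scalar AP in [0, 1]; 0 when num_gt is 0 or no detections.
#' @export
average_precision <- function(tp, num_gt) {
  if (num_gt == 0L || length(tp) == 0L) return(0)
  cum_tp <- cumsum(tp)
  cum_fp <- cumsum(!tp)
  recall <- cum_tp / num_gt
  precision <- cum_tp / (cum_tp + cum_fp)
  grid <- seq(0, 1, length.out = 101L)
  interp <- vapply(grid, function(r) {
    sel <- recall >= r
    if (any(sel)) max(precision[sel]) else 0
  }, numeric(1))
  mean(interp)
}

#' Evaluate detections against ground truth
#'
#' Per class and per IoU threshold: all detections of the class are pooled
#' across images, sorted by score, flagged TP/FP by per-image greedy
#' matching, and summarized by 101-point interpolated AP. `ap_mean`
#' averages the per-threshold class means over thresholds 0.50/0.75/0.95
#' ("literal" mode) or 0.50:0.95 in steps of 0.05 ("coco" mode).
#' `m_recall` is the mean over classes of the final recall at IoU 0.5.
#' Classes with no ground truth anywhere are excluded from all means.
#'
#' @param dets_by_image List per image: list(boxes, scores, classes).
#' @param gts_by_image List per image: list(boxes, classes).
#' @param num_classes Number of classes K.
#' @param mode "literal" or "coco" threshold set for ap_mean.
#' @param measure Overlap measure for matching, "iou" (default) or
#'   "soft_iou".
#' @param si_config A [soft_iou_config()].
#' @return An object of class "eval_result": per_class_ap (K x T matrix),
#'   ap50, ap75, ap_mean, m_recall (all in [0, 1]).
#' @export
evaluate_detections <- function(dets_by_image, gts_by_image, num_classes,
                                mode = c("literal", "coco"),
                                measure = c("iou", "soft_iou"),
                                si_config = soft_iou_config()) {
  mode <- match.arg(mode)
  measure <- match.arg(measure)
  stopifnot(length(dets_by_image) == length(gts_by_image))
  thresholds <- if (mode == "literal") c(0.50, 0.75, 0.95)
                else seq(0.50, 0.95, by = 0.05)
  extra <- setdiff(c(0.50, 0.75), thresholds)
  all_thr <- sort(unique(c(thresholds, extra)))
  K <- num_classes
  ap <- matrix(NA_real_, K, length(all_thr),
               dimnames = list(NULL, sprintf("%.2f", all_thr)))
  recall_final <- rep(NA_real_, K)
  gt_count <- integer(K)
  for (g in gts_by_image) {
    if (NROW(g$boxes) > 0L) {
      tab <- tabulate(g$classes, nbins = K)
      gt_count <- gt_count + tab
    }
  }
  for (ti in seq_along(all_thr)) {
    thr <- all_thr[ti]
    match_by_image <- lapply(seq_along(dets_by_image), function(i) {
      d <- dets_by_image[[i]]; g <- gts_by_image[[i]]
      match_detections(d$boxes, d$scores, d$classes,
                       g$boxes, g$classes, iou_threshold = thr,
                       measure = measure, si_config = si_config)
    })
    for (k in seq_len(K)) {
      if (gt_count[k] == 0L) next
      scores <- list(); flags <- list()
      for (i in seq_along(dets_by_image)) {
        d <- dets_by_image[[i]]
        mt <- match_by_image[[i]]
        cls_sorted <- d$classes[mt$order]
        sel <- cls_sorted == k
        if (!any(sel)) next
        scores[[length(scores) + 1L]] <- d$scores[mt$order][sel]
        flags[[length(flags) + 1L]] <- mt$tp[sel]
      }
      sc <- unlist(scores); fl <- unlist(flags)
      if (length(sc) == 0L) {
        ap[k, ti] <- 0
        if (abs(thr - 0.5) < 1e-9) recall_final[k] <- 0
        next
      }
      o <- order(sc, decreasing = TRUE)
      ap[k, ti] <- average_precision(fl[o], gt_count[k])
      if (abs(thr - 0.5) < 1e-9) {
        recall_final[k] <- sum(fl) / gt_count[k]
      }
    }
  }
  valid <- gt_count > 0L
  mean_over <- function(thr) {
    col <- which(abs(all_thr - thr) < 1e-9)
    mean(ap[valid, col])
  }
  ap_mean <- mean(vapply(thresholds, mean_over, numeric(1)))
  structure(list(per_class_ap = ap, thresholds = all_thr,
                 mode = mode,
                 ap50 = mean_over(0.50), ap75 = mean_over(0.75),
                 ap_mean = ap_mean,
                 m_recall = mean(recall_final[valid]),
                 gt_count = gt_count),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("Detection metrics (%s thresholds, x100):\n", x$mode))
  cat(sprintf("  AP   %6.1f\n  AP50 %6.1f\n  AP75 %6.1f\n  mRec %6.1f\n",
              100 * x$ap_mean, 100 * x$ap50, 100 * x$ap75,
              100 * x$m_recall))
  valid <- x$gt_count > 0L
  if (any(valid)) {
    cat("  per-class AP50:\n")
    col <- which(abs(x$thresholds - 0.5) < 1e-9)
    for (k in which(valid)) {
      cat(sprintf("    class %2d: %5.1f  (n_gt = %d)\n",
                  k, 100 * x$per_class_ap[k, col], x$gt_count[k]))
    }
  }
  invisible(x)
}
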