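# Box geometry and the Soft-IoU overlap score.
#
# Boxes are axis-aligned rectangles in continuous, 0-based pixel coordinates
# with corner convention (x1, y1) = top-left, (x2, y2) = bottom-right and
# area (x2 - x1) * (y2 - y1) (no +1; continuous geometry, matching COCO).
# A box is a numeric vector c(x1, y1, x2, y2); a box set is an n x 4 matrix.

#' Validate boxes
#'
#' Checks that every box has finite coordinates and strictly positive width
#' and height. Degenerate (zero or negative side) boxes are rejected rather
#' than silently producing NaN downstream (the diagonal in the Soft-IoU
#' center-distance ratio would divide by zero).
#'
#' @param boxes Numeric vector of length 4 or an n x 4 matrix, columns
#'   x1, y1, x2, y2.
#' @return The boxes as an n x 4 matrix, invisibly usable downstream.
#' @keywords internal
as_box_matrix <- function(boxes) {
  if (is.null(dim(boxes))) {
    if (length(boxes) != 4L) stop("a box must have exactly 4 coordinates")
    boxes <- matrix(as.numeric(boxes), nrow = 1L)
  } else {
    boxes <- as.matrix(boxes)
    if (ncol(boxes) != 4L) stop("box matrix must have 4 columns (x1,y1,x2,y2)")
    storage.mode(boxes) <- "double"
  }
  if (nrow(boxes) > 0L) {
    if (any(!is.finite(boxes))) stop("box coordinates must be finite")
    w <- boxes[, 3L] - boxes[, 1L]
    h <- boxes[, 4L] - boxes[, 2L]
    if (any(w <= 0 | h <= 0)) {
      stop("degenerate box: width and height must be strictly positive")
    }
  }
  boxes
}

box_area <- function(boxes) {
  boxes <- as_box_matrix(boxes)
  (boxes[, 3L] - boxes[, 1L]) * (boxes[, 4L] - boxes[, 2L])
}

#' Intersection over Union of two boxes
#'
#' @param a,b Boxes as c(x1, y1, x2, y2) with x2 > x1, y2 > y1.
#' @return Scalar IoU in [0, 1]; 0 when the boxes are disjoint.
#' @examples
#' box_iou(c(0, 0, 10, 10), c(0, 0, 10, 5))  # 0.5
#' @export
box_iou <- function(a, b) {
  pairwise_iou(a, b)[1L, 1L]
}

#' Pairwise IoU matrix
#'
#' @param boxes_a,boxes_b Box matrices (n x 4 and m x 4). Either may be
#'   empty, giving an empty matrix.
#' @return n x m matrix of IoU values.
#' @export
pairwise_iou <- function(boxes_a, boxes_b) {
  a <- as_box_matrix(boxes_a)
  b <- as_box_matrix(boxes_b)
  n <- nrow(a); m <- nrow(b)
  if (n == 0L || m == 0L) return(matrix(numeric(0), n, m))
  ix1 <- outer(a[, 1L], b[, 1L], pmax)
  iy1 <- outer(a[, 2L], b[, 2L], pmax)
  ix2 <- outer(a[, 3L], b[, 3L], pmin)
  iy2 <- outer(a[, 4L], b[, 4L], pmin)
  iw <- pmax(ix2 - ix1, 0)
  ih <- pmax(iy2 - iy1, 0)
  inter <- iw * ih
  union <- outer(box_area(a), box_area(b), `+`) - inter
  inter / union
}

#' Center-distance ratio between two boxes
#'
#' Euclidean distance between the box centers divided by the larger of the
#' two box diagonals. This is the position penalty inside the Soft-IoU
#' score: 0 for coincident centers, growing as the centers drift apart.
#'
#' @inheritParams box_iou
#' @return Non-negative scalar.
#' @export
center_distance_ratio <- function(a, b) {
  pairwise_center_distance_ratio(a, b)[1L, 1L]
}

pairwise_center_distance_ratio <- function(boxes_a, boxes_b) {
  a <- as_box_matrix(boxes_a)
  b <- as_box_matrix(boxes_b)
  n <- nrow(a); m <- nrow(b)
  if (n == 0L || m == 0L) return(matrix(numeric(0), n, m))
  acx <- (a[, 1L] + a[, 3L]) / 2; acy <- (a[, 2L] + a[, 4L]) / 2
  bcx <- (b[, 1L] + b[, 3L]) / 2; bcy <- (b[, 2L] + b[, 4L]) / 2
  d <- sqrt(outer(acx, bcx, `-`)^2 + outer(acy, bcy, `-`)^2)
  diag_a <- sqrt((a[, 3L] - a[, 1L])^2 + (a[, 4L] - a[, 2L])^2)
  diag_b <- sqrt((b[, 3L] - b[, 1L])^2 + (b[, 4L] - b[, 2L])^2)
  d / outer(diag_a, diag_b, pmax)
}

#' Soft-IoU configuration
#'
#' Phase-dependent scaling and clamping for the Soft-IoU score. During
#' training the score is shrunk (beta < 1) so only well-centered candidates
#' clear the positive threshold; at test time it is inflated (beta > 1) so
#' slightly off-center duplicates are still treated as overlapping. The
#' clamp keeps the adjusted score within clamp_factor times the raw IoU.
#'
#' @param beta_train Training-phase scale factor, in (0, 1]. Default 0.9.
#' @param beta_test Test-phase scale factor, >= 1. Default 1.1.
#' @param clamp_factor Two-sided clamp half-width as a fraction of the raw
#'   IoU, in [0, 1). Default 0.1.
#' @return An object of class "soft_iou_config".
#' @export
soft_iou_config <- function(beta_train = 0.9, beta_test = 1.1,
                            clamp_factor = 0.1) {
  stopifnot(beta_train > 0, beta_train <= 1,
            beta_test >= 1,
            clamp_factor >= 0, clamp_factor < 1)
  structure(list(beta_train = beta_train, beta_test = beta_test,
                 clamp_factor = clamp_factor),
            class = "soft_iou_config")
}

#' @export
print.soft_iou_config <- function(x, ...) {
  cat(sprintf(
    "Soft-IoU config: beta_train = %g, beta_test = %g, clamp_factor = %g\n",
    x$beta_train, x$beta_test, x$clamp_factor))
  invisible(x)
}

#' Soft-IoU of two boxes
#'
#' The IoU scaled by a center-distance penalty and a phase factor beta:
#' raw = beta * (1 - center_distance_ratio) * IoU, then clipped into the
#' band [(1 - clamp_factor) * IoU, (1 + clamp_factor) * IoU]. Disjoint
#' boxes score exactly 0 for any beta.
#'
#' @inheritParams box_iou
#' @param beta Positive scale factor (0.9 in the training phase, 1.1 at
#'   test time by default; see [soft_iou_config()]).
#' @param clamp_factor Clamp half-width as a fraction of the raw IoU.
#' @return Non-negative scalar; at most (1 + clamp_factor).
#' @examples
#' soft_iou(c(0, 0, 10, 10), c(0, 0, 10, 10), beta = 0.9)  # 0.9
#' @export
soft_iou <- function(a, b, beta = 0.9, clamp_factor = 0.1) {
  pairwise_soft_iou(a, b, beta = beta, clamp_factor = clamp_factor)[1L, 1L]
}

#' Pairwise Soft-IoU matrix
#'
#' Entry (i, j) equals soft_iou(boxes_a[i, ], boxes_b[j, ], ...). Used for
#' vectorized candidate-to-ground-truth assignment and Soft-IoU NMS.
#'
#' @inheritParams pairwise_iou
#' @inheritParams soft_iou
#' @return n x m matrix; empty inputs give an empty matrix.
#' @export
pairwise_soft_iou <- function(boxes_a, boxes_b, beta = 0.9,
                              clamp_factor = 0.1) {
  stopifnot(beta > 0, clamp_factor >= 0, clamp_factor < 1)
  iou <- pairwise_iou(boxes_a, boxes_b)
  if (length(iou) == 0L) return(iou)
  ratio <- pairwise_center_distance_ratio(boxes_a, boxes_b)
  raw <- beta * (1 - ratio) * iou
  pmin(pmax(raw, (1 - clamp_factor) * iou), (1 + clamp_factor) * iou)
}

#' Non-maximum suppression
#'
#' Greedy NMS over a set of scored boxes: the highest-scoring box is kept
#' and every remaining box whose overlap with it reaches `threshold` is
#' discarded; repeat. The overlap measure is either plain IoU or the
#' Soft-IoU (with the test-phase beta), which tolerates center-shifted
#' near-duplicates: a pair with displaced centers can fall below the
#' threshold under Soft-IoU while plain IoU would suppress it.
#'
#' @param boxes n x 4 box matrix.
#' @param scores Numeric vector of length n.
#' @param threshold Overlap threshold at or above which a box is suppressed.
#' @param measure "iou" or "soft_iou".
#' @param beta,clamp_factor Soft-IoU parameters (used when
#'   measure = "soft_iou").
#' @return Integer indices of the kept boxes, in decreasing score order.
#' @export
nms <- function(boxes, scores, threshold = 0.5,
                measure = c("iou", "soft_iou"),
                beta = 1.1, clamp_factor = 0.1) {
  measure <- match.arg(measure)
  boxes <- as_box_matrix(boxes)
  n <- nrow(boxes)
  if (n == 0L) return(integer(0))
  stopifnot(length(scores) == n)
  ov <- if (measure == "iou") pairwise_iou(boxes, boxes)
        else pairwise_soft_iou(boxes, boxes, beta = beta,
                               clamp_factor = clamp_factor)
  ord <- order(scores, decreasing = TRUE)
  keep <- integer(0)
  alive <- rep(TRUE, n)
  for (i in ord) {
    if (!alive[i]) next
    keep <- c(keep, i)
    alive[ov[i, ] >= threshold] <- FALSE
    alive[i] <- FALSE
  }
  keep
}

# Clip boxes to image bounds [0,w] x [0,h]; drops nothing, degenerate
# results are flagged by the caller.
clip_boxes <- function(boxes, image_size) {
  b <- boxes
  b[, c(1L, 3L)] <- pmin(pmax(b[, c(1L, 3L)], 0), image_size[2L])
  b[, c(2L, 4L)] <- pmin(pmax(b[, c(2L, 4L)], 0), image_size[1L])
  b
}
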