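# Shared fixtures and independent oracles used across the suite.

# Sum of absolute values per numeric leaf of a nested list (arrays
# included; NULL leaves dropped).
leaf_abs_sums <- function(g) {
  if (is.list(g)) return(unlist(lapply(g, leaf_abs_sums)))
  if (is.null(g)) return(numeric(0))
  sum(abs(g))
}

# Random valid boxes with corners in [0, extent]^2.
random_boxes <- function(n, extent = 100, min_side = 1) {
  x1 <- runif(n, 0, extent - min_side)
  y1 <- runif(n, 0, extent - min_side)
  w <- runif(n, min_side, extent / 2)
  h <- runif(n, min_side, extent / 2)
  cbind(x1, y1, pmin(x1 + w, extent), pmin(y1 + h, extent))
}

# Scalar IoU computed independently (direct geometry, no package calls).
oracle_iou <- function(a, b) {
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  area <- function(z) (z[3] - z[1]) * (z[4] - z[2])
  inter / (area(a) + area(b) - inter)
}

# Scalar Soft-IoU from first principles.
oracle_soft_iou <- function(a, b, beta, clamp = 0.1) {
  iou <- oracle_iou(a, b)
  ctr <- function(z) c((z[1] + z[3]) / 2, (z[2] + z[4]) / 2)
  diag_ <- function(z) sqrt((z[3] - z[1])^2 + (z[4] - z[2])^2)
  ratio <- sqrt(sum((ctr(a) - ctr(b))^2)) / max(diag_(a), diag_(b))
  raw <- beta * (1 - ratio) * iou
  min(max(raw, (1 - clamp) * iou), (1 + clamp) * iou)
}

# Brute-force O(N^2) positional weighting term: for each position i, the
# mean over j != i of <theta(x_j), phi(x_i)>, times g(x_i). X: H x W x C;
# maps are list(w = CxC, b = C).
oracle_local_term <- function(X, theta, phi, g) {
  d <- dim(X)
  H <- d[1]; W <- d[2]; C <- d[3]
  apply_map <- function(m, v) as.vector(m$w %*% v + m$b)
  out <- array(0, d)
  pos <- expand.grid(i = seq_len(H), j = seq_len(W))
  n <- nrow(pos)
  if (n == 1) return(out)
  for (p in seq_len(n)) {
    xi <- X[pos$i[p], pos$j[p], ]
    acc <- 0
    for (q in seq_len(n)) {
      if (q == p) next
      xj <- X[pos$i[q], pos$j[q], ]
      acc <- acc + sum(apply_map(theta, xj) * apply_map(phi, xi))
    }
    out[pos$i[p], pos$j[p], ] <- (acc / (n - 1)) * apply_map(g, xi)
  }
  out
}

# Independent detection evaluator: per-image all-pairs greedy matching and
# direct 101-point interpolated AP, written without any package matching /
# AP code. dets/gts as in evaluate_detections().
oracle_ap_per_class <- function(dets_by_image, gts_by_image, k, thr) {
  recs <- list()
  num_gt <- 0
  for (i in seq_along(dets_by_image)) {
    g <- gts_by_image[[i]]
    gsel <- which(g$classes == k)
    num_gt <- num_gt + length(gsel)
    d <- dets_by_image[[i]]
    dsel <- which(d$classes == k)
    if (length(dsel) == 0) next
    dord <- dsel[order(d$scores[dsel], decreasing = TRUE)]
    taken <- rep(FALSE, length(gsel))
    for (di in dord) {
      best <- 0; bestj <- 0
      for (jj in seq_along(gsel)) {
        if (taken[jj]) next
        ov <- oracle_iou(d$boxes[di, ], g$boxes[gsel[jj], ])
        if (ov > best) { best <- ov; bestj <- jj }
      }
      hit <- best >= thr && bestj > 0
      if (hit) taken[bestj] <- TRUE
      recs[[length(recs) + 1]] <- c(score = d$scores[di], tp = as.numeric(hit))
    }
  }
  if (num_gt == 0) return(NA_real_)
  if (length(recs) == 0) return(0)
  m <- do.call(rbind, recs)
  m <- m[order(m[, "score"], decreasing = TRUE), , drop = FALSE]
  tp <- cumsum(m[, "tp"]); fp <- cumsum(1 - m[, "tp"])
  rec <- tp / num_gt; prec <- tp / (tp + fp)
  mean(sapply(seq(0, 1, 0.01), function(r) {
    s <- prec[rec >= r]
    if (length(s)) max(s) else 0
  }))
}

# Desk-scale smoke fixture: 5 miniature scenes with object sizes that
# remain resolvable at a 128-px input.
smoke_fixture <- function(n_scenes = 5L) {
  spec <- scene_spec(image_size = c(128L, 128L), num_classes = 3L,
                     objects_per_image = c(6L, 10L),
                     relative_area = 0.03, scale_spread = 4,
                     similarity_pairs = list())
  scenes <- lapply(seq_len(n_scenes), function(i) {
    generate_scene(spec, 100L + i)
  })
  list(spec = spec,
       images = lapply(scenes, `[[`, "image"),
       annotations = lapply(scenes, function(s) {
         list(boxes = s$boxes, classes = s$classes)
       }))
}

# Random detection/gt scene pairs for evaluator cross-checks.
random_eval_scenes <- function(n_images, seed) {
  set.seed(seed)
  gts <- list(); dets <- list()
  for (i in seq_len(n_images)) {
    n_gt <- sample(2:6, 1)
    gb <- random_boxes(n_gt, extent = 200, min_side = 5)
    gc <- sample(1:3, n_gt, replace = TRUE)
    # detections: jittered copies of some gts plus pure noise
    db <- list(); dc <- integer(0); ds <- numeric(0)
    for (j in seq_len(n_gt)) {
      if (runif(1) < 0.8) {
        jit <- gb[j, ] + rnorm(4, sd = runif(1, 0.5, 6))
        jit[3] <- max(jit[3], jit[1] + 1); jit[4] <- max(jit[4], jit[2] + 1)
        db[[length(db) + 1]] <- jit
        dc <- c(dc, if (runif(1) < 0.9) gc[j] else sample(1:3, 1))
        ds <- c(ds, runif(1))
      }
    }
    n_noise <- sample(0:3, 1)
    if (n_noise > 0) {
      nb <- random_boxes(n_noise, extent = 200, min_side = 5)
      for (j in seq_len(n_noise)) db[[length(db) + 1]] <- nb[j, ]
      dc <- c(dc, sample(1:3, n_noise, replace = TRUE))
      ds <- c(ds, runif(n_noise))
    }
    gts[[i]] <- list(boxes = gb, classes = gc)
    dets[[i]] <- if (length(db)) {
      list(boxes = do.call(rbind, db), scores = ds, classes = dc)
    } else {
      list(boxes = matrix(numeric(0), 0, 4), scores = numeric(0),
           classes = integer(0))
    }
  }
  list(dets = dets, gts = gts)
}
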