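# Seeded generator of synthetic light-trap pest scenes.
#
# Emulates the object statistics of light-trap imagery: many very small
# objects (mean box area a stated small fraction of a reference
# general-object box), a wide between-class size spread (largest class
# mean area a fixed multiple of the smallest), dense and sparse layouts on
# a bright board background, and configurable high-similarity class pairs
# (two classes differing by a small perturbation of one appearance
# parameter). Pests are rendered as textured rotated ellipses with
# class-specific size, aspect ratio, color and stripe frequency;
# annotations are tight boxes around the rendered extent.

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Scene specification
#'
#' @param image_size c(height, width) in pixels.
#' @param num_classes Number of pest classes K.
#' @param objects_per_image c(min, max) objects per scene (uniform).
#' @param relative_area Target mean box area as a fraction of the
#'   reference general-object box. Default 0.0158.
#' @param scale_spread Target ratio of the largest to the smallest class
#'   mean box area. Default 32.
#' @param similarity_pairs List of length-2 integer vectors; the second
#'   class of each pair copies the first's appearance except for a small
#'   stripe-frequency offset, creating a high-similarity regime.
#' @param similarity_eps Size of that offset.
#' @param reference_box_frac The reference general-object box, as a
#'   fraction of the image area (a stated constant; only the ratio
#'   semantics of `relative_area` matter).
#' @param area_jitter_sdlog SD of the per-object log-normal area jitter
#'   (mean-corrected so the arithmetic mean stays on target).
#' @param mist_sigma Gaussian blur applied to the finished scene
#'   (simulates condensation mist on the camera); 0 disables.
#' @param noise_sd Background pixel noise SD.
#' @param class_seed Seed of the deterministic per-class appearance table.
#' @return An object of class "scene_spec".
#' @export
scene_spec <- function(image_size = c(800L, 1088L), num_classes = 8L,
                       objects_per_image = c(4L, 30L),
                       relative_area = 0.0158, scale_spread = 32,
                       similarity_pairs = list(c(5L, 6L)),
                       similarity_eps = 0.3,
                       reference_box_frac = 0.38,
                       area_jitter_sdlog = 0.25,
                       mist_sigma = 0, noise_sd = 0.015,
                       class_seed = 20L) {
  stopifnot(all(image_size >= 64), num_classes >= 1,
            objects_per_image[1L] >= 1,
            objects_per_image[2L] >= objects_per_image[1L],
            relative_area > 0, relative_area < 1, scale_spread >= 1,
            mist_sigma >= 0)
  spec <- structure(list(image_size = as.integer(image_size),
                         num_classes = as.integer(num_classes),
                         objects_per_image = as.integer(objects_per_image),
                         relative_area = relative_area,
                         scale_spread = scale_spread,
                         similarity_pairs = similarity_pairs,
                         similarity_eps = similarity_eps,
                         reference_box_frac = reference_box_frac,
                         area_jitter_sdlog = area_jitter_sdlog,
                         mist_sigma = mist_sigma, noise_sd = noise_sd,
                         class_seed = as.integer(class_seed)),
                    class = "scene_spec")
  spec$classes <- class_table(spec)
  spec
}

# Deterministic per-class appearance: mean box area (geometrically spaced
# so largest/smallest = scale_spread, overall mean = relative_area *
# reference box), aspect ratio, base color, stripe frequency.
class_table <- function(spec) {
  K <- spec$num_classes
  g <- if (K == 1L) 1 else spec$scale_spread^((seq_len(K) - 1L) / (K - 1L))
  ref_area <- spec$reference_box_frac * prod(spec$image_size)
  mean_area <- spec$relative_area * ref_area * g / mean(g)
  with_seed(spec$class_seed, {
    aspect <- stats::runif(K, 1.3, 2.4)
    stripe_freq <- stats::runif(K, 2, 6)
    # dark insect-like palette against the bright board
    hue <- stats::runif(K, 0.02, 0.35)
    sat <- stats::runif(K, 0.5, 0.9)
    val <- stats::runif(K, 0.15, 0.45)
    base_col <- grDevices::hsv(hue, sat, val)
  })
  tab <- data.frame(class_id = seq_len(K), mean_area = mean_area,
                    aspect = aspect, stripe_freq = stripe_freq,
                    color = base_col, stringsAsFactors = FALSE)
  for (p in spec$similarity_pairs) {
    a <- p[1L]; b <- p[2L]
    if (a <= K && b <= K) {
      tab$aspect[b] <- tab$aspect[a]
      tab$color[b] <- tab$color[a]
      tab$mean_area[b] <- tab$mean_area[a]
      tab$stripe_freq[b] <- tab$stripe_freq[a] + spec$similarity_eps
    }
  }
  tab
}

render_background <- function(spec) {
  H <- spec$image_size[1L]; W <- spec$image_size[2L]
  yy <- (seq_len(H) - H / 2) / H
  xx <- (seq_len(W) - W / 2) / W
  r2 <- outer(yy^2, xx^2, `+`)
  shade <- 1 - 0.18 * r2 / max(r2)
  base <- c(0.93, 0.91, 0.84)
  img <- array(0, c(H, W, 3L))
  for (c in 1:3) {
    img[, , c] <- base[c] * shade +
      stats::rnorm(H * W, sd = spec$noise_sd)
  }
  pmin(pmax(img, 0), 1)
}

# Render one elliptical pest into img; returns list(img, box) or NULL if
# the rendered mask is empty. Subpixel (2x2) coverage gives antialiased
# edges and a tight, nearly unbiased bounding box.
render_pest <- function(img, cx, cy, sa, sb, angle, col_rgb, stripe_freq) {
  H <- dim(img)[1L]; W <- dim(img)[2L]
  ct <- cos(angle); st <- sin(angle)
  half_w <- sqrt((sa * ct)^2 + (sb * st)^2)
  half_h <- sqrt((sa * st)^2 + (sb * ct)^2)
  j0 <- max(1L, floor(cx - half_w)); j1 <- min(W, ceiling(cx + half_w) + 1L)
  i0 <- max(1L, floor(cy - half_h)); i1 <- min(H, ceiling(cy + half_h) + 1L)
  if (j1 < j0 || i1 < i0) return(NULL)
  jj <- j0:j1; ii <- i0:i1
  # pixel j covers x in [j-1, j); subpixel centers at j-1+0.25, j-1+0.75
  frac <- matrix(0, length(ii), length(jj))
  ucen <- matrix(0, length(ii), length(jj))
  for (oy in c(0.25, 0.75)) {
    for (ox in c(0.25, 0.75)) {
      px <- outer(rep(1, length(ii)), jj - 1 + ox) - cx
      py <- outer(ii - 1 + oy, rep(1, length(jj))) - cy
      u <- px * ct + py * st
      v <- -px * st + py * ct
      inside <- (u / sa)^2 + (v / sb)^2 <= 1
      frac <- frac + inside / 4
    }
  }
  if (!any(frac > 0)) return(NULL)
  pxc <- outer(rep(1, length(ii)), jj - 0.5) - cx
  pyc <- outer(ii - 0.5, rep(1, length(jj))) - cy
  ucen <- pxc * ct + pyc * st
  stripes <- 1 - 0.35 * (0.5 + 0.5 * sin(pi * stripe_freq * ucen / sa))
  shade <- 1 + stats::rnorm(1, sd = 0.08)
  for (c in 1:3) {
    layer <- img[ii, jj, c]
    colm <- pmin(pmax(col_rgb[c] * stripes * shade +
                        stats::rnorm(length(layer), sd = 0.02), 0), 1)
    img[ii, jj, c] <- layer * (1 - frac) + colm * frac
  }
  hit_j <- which(colSums(frac) > 0)
  hit_i <- which(rowSums(frac) > 0)
  box <- c(jj[hit_j[1L]] - 1, ii[hit_i[1L]] - 1,
           jj[hit_j[length(hit_j)]], ii[hit_i[length(hit_i)]])
  list(img = img, box = box)
}

#' Generate one synthetic light-trap scene
#'
#' @param spec A [scene_spec()].
#' @param seed Integer seed; the same seed reproduces the scene
#'   bit-identically.
#' @return List: `image` (H x W x 3 array in [0, 1]), `boxes` (n x 4
#'   matrix, x1/y1/x2/y2, inside the image), `classes` (integer vector).
#' @export
generate_scene <- function(spec, seed = 1L) {
  with_seed(seed, {
    img <- render_background(spec)
    H <- spec$image_size[1L]; W <- spec$image_size[2L]
    n <- sample(spec$objects_per_image[1L]:spec$objects_per_image[2L], 1L)
    tab <- spec$classes
    boxes <- matrix(numeric(0), 0L, 4L)
    classes <- integer(0)
    for (o in seq_len(n)) {
      placed <- FALSE
      for (attempt in 1:15) {
        k <- sample.int(spec$num_classes, 1L)
        sdl <- spec$area_jitter_sdlog
        area <- stats::rlnorm(1, log(tab$mean_area[k]) - sdl^2 / 2, sdl)
        angle <- stats::runif(1, 0, pi)
        r <- tab$aspect[k]
        ct <- cos(angle); st <- sin(angle)
        # choose semi-axes so the rotated tight box has the sampled area
        q <- sqrt((r^2 * ct^2 + st^2) * (r^2 * st^2 + ct^2))
        sb <- sqrt(area / (4 * q))
        sa <- r * sb
        half_w <- sqrt((sa * ct)^2 + (sb * st)^2)
        half_h <- sqrt((sa * st)^2 + (sb * ct)^2)
        if (2 * half_w > W - 4 || 2 * half_h > H - 4) next
        cx <- stats::runif(1, half_w + 1, W - half_w - 1)
        cy <- stats::runif(1, half_h + 1, H - half_h - 1)
        cand <- c(cx - half_w, cy - half_h, cx + half_w, cy + half_h)
        if (nrow(boxes) > 0L &&
            max(pairwise_iou(matrix(cand, 1L), boxes)) > 0.3) next
        col_rgb <- grDevices::col2rgb(tab$color[k])[, 1L] / 255
        res <- render_pest(img, cx, cy, sa, sb, angle, col_rgb,
                           tab$stripe_freq[k])
        if (is.null(res)) next
        img <- res$img
        boxes <- rbind(boxes, res$box)
        classes <- c(classes, k)
        placed <- TRUE
        break
      }
      if (!placed) {
        warning("could not place object ", o, " after 15 attempts; skipped")
      }
    }
    if (spec$mist_sigma > 0) img <- degrade_mist(img, spec$mist_sigma)
    rownames(boxes) <- NULL
    list(image = img, boxes = boxes, classes = classes)
  })
}

gaussian_kernel_2d <- function(sigma) {
  r <- max(1L, ceiling(2.5 * sigma))
  x <- (-r):r
  k1 <- exp(-x^2 / (2 * sigma^2))
  k2 <- outer(k1, k1)
  k2 / sum(k2)
}

#' Simulate camera mist
#'
#' Gaussian blur (border-renormalized) plus mild contrast reduction.
#' sigma = 0 returns the image unchanged; pixel-intensity variance is
#' non-increasing in sigma. Annotations are unaffected by construction.
#'
#' @param image H x W x 3 array.
#' @param sigma Blur SD in pixels, >= 0.
#' @return Degraded image, same shape.
#' @export
degrade_mist <- function(image, sigma) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(image)
  k2 <- gaussian_kernel_2d(sigma)
  r <- (nrow(k2) - 1L) %/% 2L
  w <- array(k2, c(nrow(k2), ncol(k2), 1L, 1L))
  d <- dim(image)
  ones <- array(1, c(d[1L], d[2L], 1L))
  norm <- .cpp_conv2d_fwd(ones, w, 0, 1L, r)  # border renormalization
  out <- image
  for (c in 1:3) {
    ch <- array(image[, , c], c(d[1L], d[2L], 1L))
    out[, , c] <- .cpp_conv2d_fwd(ch, w, 0, 1L, r) / norm
  }
  contrast <- 1 / (1 + 0.15 * sigma)
  m <- mean(out)
  pmin(pmax(m + (out - m) * contrast, 0), 1)
}

#' Generate a dataset of scenes with COCO annotations
#'
#' Renders `n_images` scenes, writes them as PNG files plus COCO-format
#' ground-truth JSON, split into train/test by a seeded shuffle.
#'
#' @param spec A [scene_spec()].
#' @param n_images Number of scenes (>= 2).
#' @param out_dir Output directory (created if needed); images go to
#'   out_dir/images, annotations to annotations_train.json /
#'   annotations_test.json.
#' @param split_fraction Train fraction. Default 0.8.
#' @param seed Integer seed governing scenes and split.
#' @return Invisible list: per-image scene annotations, file names, the
#'   train/test index split and the JSON paths.
#' @export
generate_dataset <- function(spec, n_images, out_dir,
                             split_fraction = 0.8, seed = 1L) {
  stopifnot(n_images >= 2)
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  scene_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                            n_images))
  scenes <- vector("list", n_images)
  files <- character(n_images)
  for (i in seq_len(n_images)) {
    sc <- generate_scene(spec, scene_seeds[i])
    files[i] <- sprintf("img_%05d.png", i)
    png::writePNG(sc$image, file.path(out_dir, "images", files[i]))
    scenes[[i]] <- list(boxes = sc$boxes, classes = sc$classes)
  }
  shuffled <- with_seed(seed + 1L, sample.int(n_images))
  n_train <- round(split_fraction * n_images)
  train_idx <- sort(shuffled[seq_len(n_train)])
  test_idx <- sort(shuffled[-seq_len(n_train)])
  paths <- list(
    train = file.path(out_dir, "annotations_train.json"),
    test = file.path(out_dir, "annotations_test.json"))
  write_coco_gt(scenes[train_idx], files[train_idx], spec$image_size,
                spec$num_classes, paths$train, image_ids = train_idx)
  write_coco_gt(scenes[test_idx], files[test_idx], spec$image_size,
                spec$num_classes, paths$test, image_ids = test_idx)
  invisible(list(scenes = scenes, files = files, train = train_idx,
                 test = test_idx, paths = paths,
                 images_dir = file.path(out_dir, "images")))
}
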