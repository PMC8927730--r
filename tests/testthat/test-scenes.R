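# Synthetic scene generator: determinism, box validity, target statistics,
# mist degradation, dataset round-trip.

test_that("scenes are deterministic and boxes valid and in-bounds", {
  spec <- scene_spec(image_size = c(160L, 200L), num_classes = 4L,
                     objects_per_image = c(3L, 8L))
  s1 <- generate_scene(spec, 9L)
  s2 <- generate_scene(spec, 9L)
  expect_identical(s1, s2)
  expect_true(all(s1$image >= 0 & s1$image <= 1))
  expect_gte(nrow(s1$boxes), 1L)
  b <- s1$boxes
  expect_true(all(b[, 3] > b[, 1] & b[, 4] > b[, 2]))
  expect_true(all(b[, 1] >= 0 & b[, 2] >= 0 & b[, 3] <= 200 & b[, 4] <= 160))
  expect_true(all(s1$classes >= 1 & s1$classes <= 4))
  s3 <- generate_scene(spec, 10L)
  expect_false(identical(s1$image, s3$image))
})

test_that("realized object statistics track the generator's own targets", {
  # scale-free statistics checked at a reduced canvas for speed
  spec <- scene_spec(image_size = c(400L, 544L), num_classes = 8L,
                     objects_per_image = c(4L, 20L))
  areas <- list(); classes <- integer(0)
  for (s in 1:120) {
    sc <- generate_scene(spec, 5000L + s)
    a <- (sc$boxes[, 3] - sc$boxes[, 1]) * (sc$boxes[, 4] - sc$boxes[, 2])
    areas[[s]] <- a
    classes <- c(classes, sc$classes)
  }
  a <- unlist(areas)
  ref <- spec$reference_box_frac * prod(spec$image_size)
  rel <- mean(a) / ref
  expect_gt(rel, spec$relative_area * 0.7)
  expect_lt(rel, spec$relative_area * 1.3)
  class_means <- tapply(a, classes, mean)
  spread <- max(class_means) / min(class_means)
  expect_gt(spread, spec$scale_spread * 0.8)
  expect_lt(spread, spec$scale_spread * 1.2)
})

test_that("similarity pairs share appearance except one parameter", {
  spec <- scene_spec(num_classes = 6L, similarity_pairs = list(c(2L, 3L)),
                     similarity_eps = 0.3)
  tab <- spec$classes
  expect_equal(tab$color[2L], tab$color[3L])
  expect_equal(tab$aspect[2L], tab$aspect[3L])
  expect_equal(tab$mean_area[2L], tab$mean_area[3L])
  expect_equal(tab$stripe_freq[3L] - tab$stripe_freq[2L], 0.3)
})

test_that("mist degradation is identity at zero and contracts variance", {
  spec <- scene_spec(image_size = c(96L, 96L), num_classes = 3L,
                     objects_per_image = c(3L, 6L))
  img <- generate_scene(spec, 3L)$image
  expect_identical(degrade_mist(img, 0), img)
  v <- vapply(c(0, 0.5, 1, 2, 4), function(s) var(as.vector(
    degrade_mist(img, s))), numeric(1))
  expect_true(all(diff(v) <= 1e-12))
})

test_that("datasets split, serialize and round-trip through COCO JSON", {
  tmp <- tempfile("ds")
  spec <- scene_spec(image_size = c(96L, 96L), num_classes = 3L,
                     objects_per_image = c(2L, 5L))
  ds <- generate_dataset(spec, 10L, tmp, split_fraction = 0.8, seed = 2L)
  expect_length(ds$train, 8L)
  expect_length(ds$test, 2L)
  expect_length(list.files(file.path(tmp, "images")), 10L)
  gt <- read_coco_gt(ds$paths$train)
  expect_equal(nrow(gt$images), 8L)
  n_ann <- sum(vapply(ds$scenes[ds$train], function(s) nrow(s$boxes),
                      numeric(1)))
  expect_equal(sum(vapply(gt$by_image, function(b) nrow(b$boxes),
                          numeric(1))), n_ann)
  # boxes round-trip exactly through the [x, y, w, h] representation
  for (i in seq_along(ds$train)) {
    orig <- ds$scenes[[ds$train[i]]]
    got <- gt$by_image[[as.character(ds$train[i])]]
    expect_equal(got$boxes, orig$boxes, tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(got$classes, orig$classes)
  }
  # self-consistency: ground truth as perfect detections scores AP 1
  dets <- lapply(gt$by_image, function(g) {
    list(boxes = g$boxes, scores = rep(1, nrow(g$boxes)),
         classes = g$classes)
  })
  res <- evaluate_detections(unname(dets), unname(gt$by_image), 3L)
  expect_equal(res$ap50, 1)
  expect_equal(res$ap_mean, 1)
})
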