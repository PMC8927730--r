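# COCO-format detection JSON (ground truth and results dialects).
# Boxes on disk are [x, y, width, height]; in memory they are
# (x1, y1, x2, y2) matrices.

xyxy_to_xywh <- function(b) cbind(b[, 1L], b[, 2L],
                                  b[, 3L] - b[, 1L], b[, 4L] - b[, 2L])
xywh_to_xyxy <- function(b) cbind(b[, 1L], b[, 2L],
                                  b[, 1L] + b[, 3L], b[, 2L] + b[, 4L])

#' Write COCO ground-truth JSON
#'
#' @param scenes List per image of list(boxes = n x 4 xyxy matrix,
#'   classes = integer vector).
#' @param file_names Image file names, same length.
#' @param image_size c(height, width) shared by all images.
#' @param num_classes Number of categories (ids 1..K).
#' @param path Output JSON path.
#' @param image_ids Optional integer ids (default 1..n).
#' @return `path`, invisibly.
#' @export
write_coco_gt <- function(scenes, file_names, image_size, num_classes,
                          path, image_ids = NULL) {
  n <- length(scenes)
  if (is.null(image_ids)) image_ids <- seq_len(n)
  images <- data.frame(id = as.integer(image_ids),
                       file_name = as.character(file_names),
                       height = rep(as.integer(image_size[1L]), n),
                       width = rep(as.integer(image_size[2L]), n))
  anns <- list()
  aid <- 0L
  for (i in seq_len(n)) {
    b <- scenes[[i]]$boxes
    if (NROW(b) == 0L) next
    xywh <- xyxy_to_xywh(as_box_matrix(b))
    for (r in seq_len(nrow(xywh))) {
      aid <- aid + 1L
      anns[[aid]] <- list(id = aid, image_id = as.integer(image_ids[i]),
                          category_id = as.integer(scenes[[i]]$classes[r]),
                          bbox = as.numeric(xywh[r, ]),
                          area = xywh[r, 3L] * xywh[r, 4L],
                          iscrowd = 0L)
    }
  }
  obj <- list(images = images,
              annotations = anns,
              categories = data.frame(
                id = seq_len(num_classes),
                name = sprintf("pest_%02d", seq_len(num_classes))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read COCO ground-truth JSON
#'
#' @param path JSON file written by [write_coco_gt()] or any COCO
#'   detection ground-truth file.
#' @return List: `images` (data.frame id/file_name/height/width),
#'   `by_image` (named by image id: list(boxes xyxy, classes)),
#'   `categories` (data.frame).
#' @export
read_coco_gt <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = TRUE)
  images <- obj$images
  anns <- obj$annotations
  by_image <- lapply(images$id, function(iid) {
    if (is.data.frame(anns) && nrow(anns) > 0L) {
      sel <- anns$image_id == iid
      if (any(sel)) {
        bb <- do.call(rbind, anns$bbox[sel])
        return(list(boxes = xywh_to_xyxy(bb),
                    classes = as.integer(anns$category_id[sel])))
      }
    }
    list(boxes = matrix(numeric(0), 0L, 4L), classes = integer(0))
  })
  names(by_image) <- as.character(images$id)
  list(images = images, by_image = by_image, categories = obj$categories)
}

#' Write detections as COCO results JSON
#'
#' @param dets_by_image Named list (names = image ids as characters) of
#'   data.frames from [infer()] (columns x1..y2, class_id, score).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_coco_results <- function(dets_by_image, path) {
  rows <- list()
  for (iid in names(dets_by_image)) {
    d <- dets_by_image[[iid]]
    if (NROW(d) == 0L) next
    for (r in seq_len(nrow(d))) {
      rows[[length(rows) + 1L]] <- list(
        image_id = as.integer(iid),
        category_id = as.integer(d$class_id[r]),
        bbox = c(d$x1[r], d$y1[r], d$x2[r] - d$x1[r], d$y2[r] - d$y1[r]),
        score = d$score[r])
    }
  }
  jsonlite::write_json(rows, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read COCO results JSON
#'
#' @param path Results file from [write_coco_results()].
#' @return Named list per image id of list(boxes xyxy, scores, classes).
#' @export
read_coco_results <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (length(obj) == 0L || NROW(obj) == 0L) return(list())
  ids <- unique(obj$image_id)
  out <- lapply(ids, function(iid) {
    sel <- obj$image_id == iid
    bb <- do.call(rbind, obj$bbox[sel])
    list(boxes = xywh_to_xyxy(bb),
         scores = as.numeric(obj$score[sel]),
         classes = as.integer(obj$category_id[sel]))
  })
  names(out) <- as.character(ids)
  out
}

#' Read an image file as an H x W x 3 array
#' @param path PNG file path.
#' @return Numeric array in [0, 1].
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}
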