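# Tiny trainable backbone and the feature-pyramid contract.
#
# A feature map is an H x W x C array with a `stride` attribute (image
# pixels per cell); a feature pyramid is an ordered list of feature maps
# with strictly doubling strides. The default backbone is deliberately
# small — an initial stride-2 stem followed by 4 stride-2 stages, giving
# the same 4-level, stride-4..32 pyramid contract that a ResNet-style
# extractor provides, but trainable on a CPU from random initialization.
# Any extractor honoring the contract can be swapped in.

#' Feature map constructor
#'
#' @param values H x W x C numeric array.
#' @param stride Image pixels per cell; one of 2, 4, 8, 16, 32, 64.
#' @return The array with class "feature_map" and a stride attribute.
#' @export
feature_map <- function(values, stride) {
  stopifnot(is.array(values), length(dim(values)) == 3L,
            stride %in% c(2L, 4L, 8L, 16L, 32L, 64L))
  structure(values, stride = as.integer(stride), class = "feature_map")
}

#' @export
print.feature_map <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("feature map %d x %d x %d, stride %d\n",
              d[1L], d[2L], d[3L], attr(x, "stride")))
  invisible(x)
}

#' Feature pyramid constructor
#'
#' @param levels List of [feature_map()] objects with strictly doubling
#'   strides.
#' @return List with class "feature_pyramid".
#' @export
feature_pyramid <- function(levels) {
  strides <- vapply(levels, function(l) attr(l, "stride"), integer(1))
  if (length(strides) > 1L &&
      !all(strides[-1L] == 2L * strides[-length(strides)])) {
    stop("pyramid strides must double level to level")
  }
  structure(levels, strides = strides, class = "feature_pyramid")
}

#' @export
print.feature_pyramid <- function(x, ...) {
  cat(sprintf("feature pyramid, %d levels\n", length(x)))
  for (l in x) {
    d <- dim(l)
    cat(sprintf("  stride %2d: %d x %d x %d\n",
                attr(l, "stride"), d[1L], d[2L], d[3L]))
  }
  invisible(x)
}

pyramid_strides <- function(p) {
  vapply(p, function(l) attr(l, "stride") %||% l$stride, integer(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Backbone configuration
#'
#' @param stage_channels Channel widths of the 4 stages (positive,
#'   non-decreasing). The stages emit the stride-4, 8, 16 and 32 levels.
#' @param stem_channels Width of the initial stride-2 stem convolution.
#' @param depth Convolutions per stage (the first is stride 2, the rest
#'   stride 1).
#' @return An object of class "backbone_config".
#' @export
backbone_config <- function(stage_channels = c(32L, 64L, 128L, 256L),
                            stem_channels = 16L, depth = 1L) {
  stopifnot(length(stage_channels) == 4L, all(stage_channels > 0),
            !is.unsorted(stage_channels), stem_channels > 0, depth >= 1L)
  structure(list(stage_channels = as.integer(stage_channels),
                 stem_channels = as.integer(stem_channels),
                 depth = as.integer(depth),
                 stage_strides = c(4L, 8L, 16L, 32L)),
            class = "backbone_config")
}

# He-normal conv weight, dims c(kh, kw, cin, cout)
init_conv <- function(kh, kw, cin, cout, sd = NULL) {
  if (is.null(sd)) sd <- sqrt(2 / (kh * kw * cin))
  list(w = array(stats::rnorm(kh * kw * cin * cout, sd = sd),
                 c(kh, kw, cin, cout)),
       b = numeric(cout))
}

#' Initialize backbone parameters
#'
#' Uses the current RNG state; seed with [set.seed()] (or pass through
#' the detector-level seed) for reproducible initialization.
#' @param config A [backbone_config()].
#' @param in_channels Number of image channels (3 for RGB).
#' @return Nested list of conv weights/biases.
#' @export
init_backbone <- function(config = backbone_config(), in_channels = 3L) {
  sc <- config$stage_channels
  params <- list(stem = init_conv(3L, 3L, in_channels, config$stem_channels))
  prev <- config$stem_channels
  for (s in 1:4) {
    stage <- list(init_conv(3L, 3L, prev, sc[s]))
    if (config$depth > 1L) {
      for (d in 2:config$depth) {
        stage[[d]] <- init_conv(3L, 3L, sc[s], sc[s])
      }
    }
    params[[paste0("stage", s)]] <- stage
    prev <- sc[s]
  }
  params
}

# Core forward: image (or node) -> list of 4 levels, each list(x, stride).
backbone_forward <- function(params, config, image) {
  x <- ad_relu(ad_conv2d(image, params$stem$w, params$stem$b,
                         stride = 2L, pad = 1L))
  out <- vector("list", 4L)
  for (s in 1:4) {
    stage <- params[[paste0("stage", s)]]
    x <- ad_relu(ad_conv2d(x, stage[[1L]]$w, stage[[1L]]$b,
                           stride = 2L, pad = 1L))
    if (length(stage) > 1L) {
      for (d in 2:length(stage)) {
        x <- ad_relu(ad_conv2d(x, stage[[d]]$w, stage[[d]]$b,
                               stride = 1L, pad = 1L))
      }
    }
    out[[s]] <- list(x = x, stride = config$stage_strides[s])
  }
  out
}

#' Extract a 4-level feature pyramid from an image
#'
#' @param image H x W x 3 numeric array with values in [0, 1]; both sides
#'   must be at least 64 pixels.
#' @param params Backbone parameters from [init_backbone()].
#' @param config The matching [backbone_config()].
#' @return A [feature_pyramid()] with 4 levels at strides 4, 8, 16, 32;
#'   each level's spatial size is ceil(image size / stride).
#' @export
extract_features <- function(image, params, config = backbone_config()) {
  d <- dim(image)
  if (is.null(d) || length(d) != 3L) stop("image must be an H x W x C array")
  if (d[1L] < 64L || d[2L] < 64L) {
    stop("image too small: both sides must be >= 64 pixels")
  }
  levels <- backbone_forward(params, config, image)
  feature_pyramid(lapply(levels, function(l) {
    feature_map(ad_value(l$x), l$stride)
  }))
}
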