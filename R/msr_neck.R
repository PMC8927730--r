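# Multi-scale super-resolution (MSR) feature-enhancement neck.
#
# Three stages, applied between backbone and detection heads:
#   1. sr_component: 1x1 lateral projections to a common width, a new
#      stride-2 level synthesized by transposed convolution of the finest
#      lateral, top-down fusion with bilinear x2 upsampling, per-level 3x3
#      smoothing, and a stride-64 level appended by stride-2 max pooling
#      (kernel 1) of the coarsest output — 4 levels in, 6 levels out.
#   2. full_fusion: every one of the 6 levels is bilinearly resized to each
#      of the 5 target grids (strides 4..64), the six same-size maps are
#      concatenated along channels, projected back to the common width by a
#      1x1 convolution, and added residually to the corresponding level.
#   3. full_weighting: a convex mixture of a non-local positional term
#      (pairwise affinities between learned per-position embeddings,
#      multiplied into a learned value projection) and a channel term
#      (rectified learned maps of the global average- and max-pooled
#      channel vectors, broadcast over positions):
#        W(X) = alpha * piL(X) g(X) + (1 - alpha) * piC(X) X.
#
# Internally a pyramid is a plain list of list(x = array-or-ad_node,
# stride = int); exported wrappers speak feature_pyramid / feature_map.

#' MSR neck configuration
#'
#' @param out_channels Common channel width of all neck levels. Default 256.
#' @param smooth_kernel Kernel size of the per-level smoothing convolution.
#' @param alpha Mixing factor of the positional vs channel weighting terms,
#'   in [0, 1]. Default 0.5.
#' @param alpha_learnable If TRUE, alpha is trained end-to-end (as a
#'   logit-free scalar clamped to [0, 1] after each update).
#' @param local_normalization "mean" divides the positional affinity sum by
#'   the number of contributing (other) positions, keeping its scale
#'   comparable across pyramid levels; "sum" leaves the raw sum.
#' @param channel_gate "literal" uses the rectified channel weights as-is
#'   (non-negative, unbounded); "sigmoid" squashes them to (0, 1) for
#'   training stability.
#' @return An object of class "msr_config".
#' @export
msr_config <- function(out_channels = 256L, smooth_kernel = 3L,
                       alpha = 0.5, alpha_learnable = FALSE,
                       local_normalization = c("mean", "sum"),
                       channel_gate = c("literal", "sigmoid")) {
  stopifnot(out_channels > 0, alpha >= 0, alpha <= 1,
            smooth_kernel %% 2L == 1L)
  structure(list(out_channels = as.integer(out_channels),
                 smooth_kernel = as.integer(smooth_kernel),
                 deconv = list(kernel = 4L, stride = 2L),
                 alpha = alpha,
                 alpha_learnable = isTRUE(alpha_learnable),
                 local_normalization = match.arg(local_normalization),
                 channel_gate = match.arg(channel_gate)),
            class = "msr_config")
}

#' Learnable maps of the full-weighting stage
#'
#' The per-position maps theta_L, phi_L (affinity embeddings) and g (value
#' projection) act on each position's C-vector; the channel maps theta_C,
#' phi_C act on the pooled C-vectors. All default to the identity with zero
#' bias, which is the configuration the closed-form examples in the tests
#' use; [init_msr_neck()] replaces them with random initializations.
#'
#' @param channels Channel count C the maps act on.
#' @param theta_L,phi_L,g,theta_C,phi_C Each a list(w = C x C matrix,
#'   b = length-C vector).
#' @return An object of class "full_weighting_params".
#' @export
full_weighting_params <- function(channels,
                                  theta_L = NULL, phi_L = NULL, g = NULL,
                                  theta_C = NULL, phi_C = NULL) {
  idmap <- function() list(w = diag(channels), b = numeric(channels))
  chk <- function(m) {
    stopifnot(is.matrix(m$w), nrow(m$w) == channels, ncol(m$w) == channels,
              length(m$b) == channels)
    m
  }
  structure(list(channels = as.integer(channels),
                 theta_L = chk(theta_L %||% idmap()),
                 phi_L = chk(phi_L %||% idmap()),
                 g = chk(g %||% idmap()),
                 theta_C = chk(theta_C %||% idmap()),
                 phi_C = chk(phi_C %||% idmap())),
            class = "full_weighting_params")
}

rand_linmap <- function(channels, sd = NULL, bias = 0) {
  if (is.null(sd)) sd <- sqrt(1 / channels)
  list(w = matrix(stats::rnorm(channels^2, sd = sd), channels, channels),
       b = rep(bias, channels))
}

#' Initialize MSR neck parameters
#'
#' @param config An [msr_config()].
#' @param in_channels Channel widths of the 4 backbone levels.
#' @return List with elements params (all learnable arrays) and config,
#'   class "msr_neck".
#' @export
init_msr_neck <- function(config = msr_config(),
                          in_channels = c(32L, 64L, 128L, 256L)) {
  C <- config$out_channels
  k <- config$smooth_kernel
  params <- list(
    lateral = lapply(in_channels, function(ci) init_conv(1L, 1L, ci, C)),
    deconv = init_conv(config$deconv$kernel, config$deconv$kernel, C, C),
    smooth = lapply(1:5, function(i) init_conv(k, k, C, C)),
    fusion = lapply(1:5, function(i) init_conv(1L, 1L, 6L * C, C)),
    # near-identity start for the weighting block: the value projection g
    # and the channel maps are initialized small (the channel maps with a
    # positive bias so the gate opens at ~1), so W(X) ~ (1-alpha) X at
    # init and the block's influence is learned rather than imposed --
    # the usual zero-init convention for attention blocks
    weighting = full_weighting_params(
      C, theta_L = rand_linmap(C), phi_L = rand_linmap(C),
      g = rand_linmap(C, sd = 0.01),
      theta_C = rand_linmap(C, sd = 0.01, bias = 0.5),
      phi_C = rand_linmap(C, sd = 0.01, bias = 0.5))
  )
  if (config$alpha_learnable) params$alpha <- config$alpha
  structure(list(params = params, config = config), class = "msr_neck")
}

#' @export
print.msr_neck <- function(x, ...) {
  cat(sprintf(
    "MSR neck: %d output channels, alpha = %s%s\n",
    x$config$out_channels,
    format(x$params$alpha %||% x$config$alpha),
    if (x$config$alpha_learnable) " (learnable)" else ""))
  invisible(x)
}

check_pyramid_contract <- function(levels, n, strides) {
  if (length(levels) != n) {
    stop(sprintf("expected a %d-level pyramid, got %d levels",
                 n, length(levels)))
  }
  got <- vapply(levels, function(l) as.integer(l$stride), integer(1))
  if (!identical(got, as.integer(strides))) {
    stop(sprintf("expected strides %s, got %s",
                 paste(strides, collapse = ","), paste(got, collapse = ",")))
  }
  invisible(NULL)
}

map_hw <- function(l) dim(ad_value(l$x))[1:2]

# ---- stage 1: super-resolution pyramid expansion --------------------------

msr_sr_core <- function(params, config, pyr4) {
  check_pyramid_contract(pyr4, 4L, c(4L, 8L, 16L, 32L))
  lat <- lapply(1:4, function(i) {
    list(x = ad_conv2d(pyr4[[i]]$x, params$lateral[[i]]$w,
                       params$lateral[[i]]$b, stride = 1L, pad = 0L),
         stride = pyr4[[i]]$stride)
  })
  p2 <- list(x = ad_conv_transpose2d(lat[[1L]]$x, params$deconv$w,
                                     params$deconv$b,
                                     stride = config$deconv$stride,
                                     pad = 1L),
             stride = 2L)
  levels <- c(list(p2), lat)  # strides 2,4,8,16,32
  for (i in 4:1) {
    up <- ad_resize_bilinear(levels[[i + 1L]]$x, map_hw(levels[[i]]))
    levels[[i]]$x <- ad_add(levels[[i]]$x, up)
  }
  pad <- (config$smooth_kernel - 1L) %/% 2L
  for (i in 1:5) {
    levels[[i]]$x <- ad_conv2d(levels[[i]]$x, params$smooth[[i]]$w,
                               params$smooth[[i]]$b, stride = 1L, pad = pad)
  }
  p64 <- list(x = ad_subsample2(levels[[5L]]$x), stride = 64L)
  c(levels, list(p64))
}

# ---- stage 2: feature full fusion -----------------------------------------

msr_fusion_core <- function(params, config, pyr6) {
  check_pyramid_contract(pyr6, 6L, c(2L, 4L, 8L, 16L, 32L, 64L))
  out <- vector("list", 5L)
  for (t in 1:5) {
    target <- pyr6[[t + 1L]]
    thw <- map_hw(target)
    resized <- lapply(pyr6, function(l) {
      if (identical(map_hw(l), thw)) l$x else ad_resize_bilinear(l$x, thw)
    })
    stacked <- ad_concat_c(resized)
    proj <- ad_conv2d(stacked, params$fusion[[t]]$w, params$fusion[[t]]$b,
                      stride = 1L, pad = 0L)
    out[[t]] <- list(x = ad_add(target$x, proj), stride = target$stride)
  }
  out
}

# ---- stage 3: feature full weighting --------------------------------------

# Positional affinity term: for each position i, the mean (or sum) over the
# other positions j of <theta_L(x_j), phi_L(x_i)>, times the value
# projection g(x_i). Returns an H x W x C map (array or node).
local_term_core <- function(X, wp, normalization = "mean") {
  d <- dim(ad_value(X))
  n <- d[1L] * d[2L]
  Xm <- ad_reshape(X, c(n, d[3L]))
  # maps act as W x + b on each position's channel vector; rows of Xm are
  # positions, hence the transpose
  theta <- ad_linear(Xm, ad_transpose(wp$theta_L$w), wp$theta_L$b)
  phi <- ad_linear(Xm, ad_transpose(wp$phi_L$w), wp$phi_L$b)
  gmap <- ad_linear(Xm, ad_transpose(wp$g$w), wp$g$b)
  a <- ad_local_affinity(theta, phi)
  if (n == 1L) {
    out <- ad_scale(gmap, 0)
  } else {
    if (normalization == "sum") a <- ad_scale(a, n - 1)
    out <- ad_mul_rows(a, gmap)
  }
  ad_reshape(out, d)
}

# Channel weights: ReLU(theta_C(avg(X))) + ReLU(phi_C(max(X))), a C-vector.
channel_term_core <- function(X, wp, gate = "literal") {
  avg <- ad_gap(X)
  mx <- ad_gmp(X)
  w <- ad_add(ad_relu(ad_linear_vec(avg, wp$theta_C$w, wp$theta_C$b)),
              ad_relu(ad_linear_vec(mx, wp$phi_C$w, wp$phi_C$b)))
  if (gate == "sigmoid") {
    v <- ad_value(w)
    s <- 1 / (1 + exp(-v))
    w <- if (is_ad_node(w)) {
      wn <- w
      new_node(s, function(g) accum_grad(wn, g * s * (1 - s)))
    } else s
  }
  w
}

full_weighting_core <- function(X, wp, alpha, config) {
  local <- local_term_core(X, wp, config$local_normalization)
  cw <- channel_term_core(X, wp, config$channel_gate)
  channel <- ad_mul_channel(X, cw)
  if (is_ad_node(alpha)) {
    one_minus <- ad_scale(ad_add(ad_scale(alpha, -1), 1), 1)
    ad_add(ad_mul_scalar(local, alpha), ad_mul_scalar(channel, one_minus))
  } else {
    ad_add(ad_scale(local, alpha), ad_scale(channel, 1 - alpha))
  }
}

msr_weight_core <- function(params, config, pyr5) {
  alpha <- params$alpha %||% config$alpha
  lapply(pyr5, function(l) {
    list(x = full_weighting_core(l$x, params$weighting, alpha, config),
         stride = l$stride)
  })
}

msr_forward_core <- function(params, config, pyr4) {
  msr_weight_core(params, config,
                  msr_fusion_core(params, config,
                                  msr_sr_core(params, config, pyr4)))
}

# ---- exported wrappers on feature_pyramid / feature_map -------------------

fp_to_internal <- function(fp) {
  lapply(fp, function(l) list(x = unclass_map(l), stride = attr(l, "stride")))
}

unclass_map <- function(m) {
  a <- m
  attributes(a) <- list(dim = dim(m))
  a
}

internal_to_fp <- function(pyr) {
  feature_pyramid(lapply(pyr, function(l) {
    feature_map(ad_value(l$x), l$stride)
  }))
}

#' Super-resolution pyramid expansion
#'
#' Expands a 4-level backbone pyramid (strides 4..32) into 6 levels
#' (strides 2..64) at a common channel width: 1x1 laterals, a transposed-
#' convolution stride-2 level, top-down bilinear fusion, 3x3 smoothing,
#' and a stride-64 max-pooled top level.
#'
#' @param backbone_pyramid A 4-level [feature_pyramid()], strides 4..32.
#' @param neck An [init_msr_neck()] object.
#' @return A 6-level [feature_pyramid()], strides 2..64.
#' @export
sr_component <- function(backbone_pyramid, neck) {
  internal_to_fp(msr_sr_core(neck$params, neck$config,
                             fp_to_internal(backbone_pyramid)))
}

#' Feature full fusion
#'
#' Resizes all 6 levels to each of the 5 target grids (strides 4..64),
#' concatenates the six same-size maps along channels, projects back to
#' the common width with a 1x1 convolution and adds the result residually
#' to the corresponding level. With zero-initialized fusion weights this
#' is exactly the identity on the stride-4..64 levels.
#'
#' @param sr_pyramid A 6-level [feature_pyramid()] from [sr_component()].
#' @param neck An [init_msr_neck()] object.
#' @return A 5-level [feature_pyramid()], strides 4..64.
#' @export
full_fusion <- function(sr_pyramid, neck) {
  internal_to_fp(msr_fusion_core(neck$params, neck$config,
                                 fp_to_internal(sr_pyramid)))
}

#' Non-local positional weighting term
#'
#' For each position i of the map, the mean over all other positions j of
#' the inner product between the embedded features theta_L(x_j) and
#' phi_L(x_i), multiplied into the value projection g(x_i). A single-
#' position map returns zeros (empty sum).
#'
#' @param X H x W x C array (a [feature_map()] works).
#' @param params A [full_weighting_params()].
#' @param normalization "mean" (divide the affinity sum by the number of
#'   other positions) or "sum".
#' @return H x W x C array.
#' @export
local_term <- function(X, params, normalization = c("mean", "sum")) {
  normalization <- match.arg(normalization)
  if (params$channels != dim(X)[3L]) {
    stop("channel mismatch between params and X")
  }
  ad_value(local_term_core(unclass_map(X), params, normalization))
}

#' Channel weighting term
#'
#' Global average- and max-pooling of the map produce two C-vectors; each
#' passes its learned channel map and a rectifier, and the two are summed
#' into a position-independent per-channel weight vector.
#'
#' @inheritParams local_term
#' @param gate "literal" (non-negative, unbounded) or "sigmoid".
#' @return Length-C numeric weight vector.
#' @export
channel_term <- function(X, params, gate = c("literal", "sigmoid")) {
  gate <- match.arg(gate)
  if (params$channels != dim(X)[3L]) {
    stop("channel mismatch between params and X")
  }
  ad_value(channel_term_core(unclass_map(X), params, gate))
}

#' Feature full weighting
#'
#' The convex mixture W(X) = alpha * local + (1 - alpha) * (channel ⊙ X)
#' of the non-local positional term and the channel-weighted map.
#'
#' @inheritParams local_term
#' @param alpha Mixing factor in [0, 1].
#' @param config An [msr_config()] (controls normalization and gating).
#' @return H x W x C array, same shape as X.
#' @export
full_weighting <- function(X, params, alpha = 0.5, config = msr_config()) {
  stopifnot(alpha >= 0, alpha <= 1)
  if (params$channels != dim(X)[3L]) {
    stop("channel mismatch between params and X")
  }
  ad_value(full_weighting_core(unclass_map(X), params, alpha, config))
}

#' Full MSR neck forward pass
#'
#' sr_component, then full_fusion, then full_weighting on every level.
#'
#' @param backbone_pyramid A 4-level [feature_pyramid()], strides 4..32.
#' @param neck An [init_msr_neck()] object.
#' @return A 5-level [feature_pyramid()], strides 4..64, at the neck's
#'   common channel width — the same contract a standard FPN neck
#'   provides, so the two are swappable by configuration.
#' @export
msr_forward <- function(backbone_pyramid, neck) {
  internal_to_fp(msr_forward_core(neck$params, neck$config,
                                  fp_to_internal(backbone_pyramid)))
}

# ---- baseline FPN neck (comparison only) ----------------------------------

#' Initialize a baseline FPN neck
#'
#' Thin comparison neck: 1x1 laterals, top-down bilinear fusion, 3x3
#' smoothing, stride-64 subsampled top level. Same 5-level contract as
#' [msr_forward()].
#' @inheritParams init_msr_neck
#' @return List with params and config, class "fpn_neck".
#' @export
init_fpn_neck <- function(config = msr_config(),
                          in_channels = c(32L, 64L, 128L, 256L)) {
  C <- config$out_channels
  k <- config$smooth_kernel
  params <- list(
    lateral = lapply(in_channels, function(ci) init_conv(1L, 1L, ci, C)),
    smooth = lapply(1:4, function(i) init_conv(k, k, C, C))
  )
  structure(list(params = params, config = config), class = "fpn_neck")
}

fpn_forward_core <- function(params, config, pyr4) {
  check_pyramid_contract(pyr4, 4L, c(4L, 8L, 16L, 32L))
  lat <- lapply(1:4, function(i) {
    list(x = ad_conv2d(pyr4[[i]]$x, params$lateral[[i]]$w,
                       params$lateral[[i]]$b, stride = 1L, pad = 0L),
         stride = pyr4[[i]]$stride)
  })
  for (i in 3:1) {
    up <- ad_resize_bilinear(lat[[i + 1L]]$x, map_hw(lat[[i]]))
    lat[[i]]$x <- ad_add(lat[[i]]$x, up)
  }
  pad <- (config$smooth_kernel - 1L) %/% 2L
  for (i in 1:4) {
    lat[[i]]$x <- ad_conv2d(lat[[i]]$x, params$smooth[[i]]$w,
                            params$smooth[[i]]$b, stride = 1L, pad = pad)
  }
  p64 <- list(x = ad_subsample2(lat[[4L]]$x), stride = 64L)
  c(lat, list(p64))
}

#' Baseline FPN forward pass
#' @inheritParams msr_forward
#' @param neck An [init_fpn_neck()] object.
#' @return A 5-level [feature_pyramid()], strides 4..64.
#' @export
fpn_forward <- function(backbone_pyramid, neck) {
  internal_to_fp(fpn_forward_core(neck$params, neck$config,
                                  fp_to_internal(backbone_pyramid)))
}
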