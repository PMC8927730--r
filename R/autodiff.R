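# Minimal tape-based reverse-mode automatic differentiation.
#
# A node is an environment of class "ad_node" holding $value (an array),
# $grad (accumulated during backward) and $backfn (a closure that pushes
# the node's grad to its parents). Ops record themselves on a global tape
# in execution order; ad_backward() walks the tape in reverse. When no
# tape is active and no input is a node, every op degrades to a plain
# array computation, so the same forward code serves training and
# inference.

.ad <- new.env(parent = emptyenv())
.ad$tape <- NULL

#' @keywords internal
is_ad_node <- function(x) inherits(x, "ad_node")

#' Value of a node or plain array
#' @param x An ad_node or a plain numeric object.
#' @return The underlying numeric value.
#' @export
ad_value <- function(x) if (is_ad_node(x)) x$value else x

ad_tape_active <- function() !is.null(.ad$tape)

#' Run an expression with a fresh autodiff tape
#'
#' Activates a tape, evaluates `expr` (typically a forward pass ending in
#' [ad_backward()]), then discards the tape. Gradients remain available in
#' the leaf nodes created with [ad_var()].
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_tape <- function(expr) {
  old <- .ad$tape
  .ad$tape <- new.env(parent = emptyenv())
  .ad$tape$nodes <- vector("list", 256L)
  .ad$tape$n <- 0L
  on.exit(.ad$tape <- old)
  expr
}

new_node <- function(value, backfn = NULL, leaf = FALSE) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$backfn <- backfn
  node$leaf <- leaf
  class(node) <- "ad_node"
  if (!leaf && ad_tape_active()) {
    tp <- .ad$tape
    tp$n <- tp$n + 1L
    if (tp$n > length(tp$nodes)) length(tp$nodes) <- 2L * length(tp$nodes)
    tp$nodes[[tp$n]] <- node
  }
  node
}

#' Create a differentiable leaf (parameter) node
#' @param value Numeric array/matrix/vector.
#' @return An ad_node whose $grad is filled in by [ad_backward()].
#' @export
ad_var <- function(value) new_node(value, leaf = TRUE)

accum_grad <- function(node, g) {
  if (!is_ad_node(node)) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

# Decide whether to track: any input a node while a tape is active.
tracking <- function(...) {
  ad_tape_active() && any(vapply(list(...), is_ad_node, logical(1)))
}

#' Reverse pass
#'
#' Seeds `loss$grad` with 1 and propagates gradients through every op
#' recorded on the active tape, in reverse order.
#' @param loss Scalar ad_node.
#' @export
ad_backward <- function(loss) {
  stopifnot(is_ad_node(loss), length(loss$value) == 1L)
  loss$grad <- 1
  tp <- .ad$tape
  if (is.null(tp)) stop("ad_backward() requires an active tape (with_tape)")
  for (i in seq(tp$n, 1L)) {
    node <- tp$nodes[[i]]
    if (!is.null(node$grad) && !is.null(node$backfn)) node$backfn(node$grad)
  }
  invisible(NULL)
}

# ---- elementwise / structural ops -----------------------------------------

ad_relu <- function(x) {
  v <- ad_value(x)
  out <- pmax(v, 0)
  if (!tracking(x)) return(out)
  mask <- v > 0
  new_node(out, function(g) accum_grad(x, g * mask))
}

ad_add <- function(x, y) {
  vx <- ad_value(x); vy <- ad_value(y)
  out <- vx + vy
  if (!tracking(x, y)) return(out)
  new_node(out, function(g) { accum_grad(x, g); accum_grad(y, g) })
}

ad_scale <- function(x, k) {
  out <- ad_value(x) * k
  if (!tracking(x)) return(out)
  new_node(out, function(g) accum_grad(x, g * k))
}

# x: H x W x C map; wvec: length-C channel weights. Broadcast multiply.
ad_mul_channel <- function(x, wvec) {
  vx <- ad_value(x); vw <- ad_value(wvec)
  d <- dim(vx)
  wb <- rep(vw, each = d[1L] * d[2L])
  out <- vx * wb
  dim(out) <- d
  if (!tracking(x, wvec)) return(out)
  new_node(out, function(g) {
    accum_grad(x, array(g * wb, d))
    accum_grad(wvec, colSums(matrix(g * vx, ncol = d[3L])))
  })
}

# map: H x W per-position scalars; x: H x W x C. Broadcast over channels.
ad_mul_pos <- function(map, x) {
  vm <- ad_value(map); vx <- ad_value(x)
  d <- dim(vx)
  mb <- array(rep(as.vector(vm), d[3L]), d)
  out <- vx * mb
  if (!tracking(map, x)) return(out)
  new_node(out, function(g) {
    accum_grad(x, g * mb)
    gm <- rowSums(matrix(g * vx, nrow = d[1L] * d[2L]))
    dim(gm) <- d[1L:2L]
    accum_grad(map, gm)
  })
}

ad_reshape <- function(x, new_dim) {
  v <- ad_value(x)
  old_dim <- dim(v)
  out <- v
  dim(out) <- new_dim
  if (!tracking(x)) return(out)
  new_node(out, function(g) {
    dim(g) <- old_dim
    accum_grad(x, g)
  })
}

ad_transpose <- function(x) {
  v <- ad_value(x)
  out <- t(v)
  if (!tracking(x)) return(out)
  new_node(out, function(g) accum_grad(x, t(g)))
}

ad_gather <- function(x, idx) {
  v <- ad_value(x)
  out <- v[idx]
  if (!tracking(x)) return(out)
  n <- length(v)
  new_node(out, function(g) {
    gx <- numeric(n)
    # scatter-add (idx may repeat)
    gs <- rowsum(as.vector(g), group = idx)
    gx[as.integer(rownames(gs))] <- gs[, 1L]
    dim(gx) <- dim(v)
    accum_grad(x, gx)
  })
}

ad_rows <- function(x, idx) {
  v <- ad_value(x)
  out <- v[idx, , drop = FALSE]
  if (!tracking(x)) return(out)
  new_node(out, function(g) {
    gx <- matrix(0, nrow(v), ncol(v))
    gs <- rowsum(g, group = idx)
    gx[as.integer(rownames(gs)), ] <- gs
    accum_grad(x, gx)
  })
}

ad_rbind <- function(xs) {
  vs <- lapply(xs, ad_value)
  out <- do.call(rbind, vs)
  if (!ad_tape_active() || !any(vapply(xs, is_ad_node, logical(1)))) {
    return(out)
  }
  nr <- vapply(vs, nrow, integer(1))
  ends <- cumsum(nr)
  starts <- ends - nr + 1L
  new_node(out, function(g) {
    for (k in seq_along(xs)) {
      if (nr[k] > 0L) {
        accum_grad(xs[[k]], g[starts[k]:ends[k], , drop = FALSE])
      }
    }
  })
}

ad_concat_c <- function(xs) {
  vs <- lapply(xs, ad_value)
  d1 <- dim(vs[[1L]])
  ch <- vapply(vs, function(v) dim(v)[3L], numeric(1))
  out <- array(unlist(vs, use.names = FALSE), c(d1[1L], d1[2L], sum(ch)))
  if (!ad_tape_active() || !any(vapply(xs, is_ad_node, logical(1)))) {
    return(out)
  }
  ends <- cumsum(ch)
  starts <- ends - ch + 1L
  new_node(out, function(g) {
    for (k in seq_along(xs)) {
      accum_grad(xs[[k]], g[, , starts[k]:ends[k], drop = FALSE])
    }
  })
}

# Stride-2 subsampling (max pooling with kernel 1): keeps cells 1,3,5,...
ad_subsample2 <- function(x) {
  v <- ad_value(x)
  d <- dim(v)
  ri <- seq(1L, d[1L], by = 2L)
  ci <- seq(1L, d[2L], by = 2L)
  out <- v[ri, ci, , drop = FALSE]
  if (!tracking(x)) return(out)
  new_node(out, function(g) {
    gx <- array(0, d)
    gx[ri, ci, ] <- g
    accum_grad(x, gx)
  })
}

# ---- pooling --------------------------------------------------------------

ad_gap <- function(x) {
  v <- ad_value(x)
  d <- dim(v)
  n <- d[1L] * d[2L]
  out <- colMeans(matrix(v, nrow = n))
  if (!tracking(x)) return(out)
  new_node(out, function(g) {
    accum_grad(x, array(rep(g / n, each = n), d))
  })
}

ad_gmp <- function(x) {
  v <- ad_value(x)
  d <- dim(v)
  n <- d[1L] * d[2L]
  m <- matrix(v, nrow = n)
  which_max <- max.col(t(m), ties.method = "first")
  out <- m[cbind(which_max, seq_len(d[3L]))]
  if (!tracking(x)) return(out)
  new_node(out, function(g) {
    gx <- array(0, d)
    gm <- matrix(gx, nrow = n)
    gm[cbind(which_max, seq_len(d[3L]))] <- g
    accum_grad(x, array(gm, d))
  })
}

# ---- linear algebra -------------------------------------------------------

# x: n x d_in; W: d_in x d_out; b: length d_out (or NULL)
ad_linear <- function(x, W, b = NULL) {
  vx <- ad_value(x); vW <- ad_value(W)
  out <- vx %*% vW
  if (!is.null(b)) out <- sweep(out, 2L, ad_value(b), `+`)
  if (!tracking(x, W, b)) return(out)
  new_node(out, function(g) {
    accum_grad(x, g %*% t(vW))
    accum_grad(W, t(vx) %*% g)
    if (!is.null(b)) accum_grad(b, colSums(g))
  })
}

# v: length C vector; W: C x C map; b: length C
ad_linear_vec <- function(v, W, b = NULL) {
  vv <- ad_value(v); vW <- ad_value(W)
  out <- as.vector(vW %*% vv)
  if (!is.null(b)) out <- out + ad_value(b)
  if (!tracking(v, W, b)) return(out)
  new_node(out, function(g) {
    accum_grad(v, as.vector(t(vW) %*% g))
    accum_grad(W, outer(g, vv))
    if (!is.null(b)) accum_grad(b, g)
  })
}

# ---- convolutional ops (C++ kernels) --------------------------------------

ad_conv2d <- function(x, w, b, stride = 1L, pad = 1L) {
  vx <- ad_value(x); vw <- ad_value(w); vb <- ad_value(b)
  out <- .cpp_conv2d_fwd(vx, vw, vb, as.integer(stride), as.integer(pad))
  if (!tracking(x, w, b)) return(out)
  new_node(out, function(g) {
    gr <- .cpp_conv2d_bwd(vx, vw, g, as.integer(stride), as.integer(pad))
    accum_grad(x, gr$dx); accum_grad(w, gr$dw); accum_grad(b, gr$db)
  })
}

ad_conv_transpose2d <- function(x, w, b, stride = 2L, pad = 1L) {
  vx <- ad_value(x); vw <- ad_value(w); vb <- ad_value(b)
  out <- .cpp_convt2d_fwd(vx, vw, vb, as.integer(stride), as.integer(pad))
  if (!tracking(x, w, b)) return(out)
  new_node(out, function(g) {
    gr <- .cpp_convt2d_bwd(vx, vw, g, as.integer(stride), as.integer(pad))
    accum_grad(x, gr$dx); accum_grad(w, gr$dw); accum_grad(b, gr$db)
  })
}

ad_resize_bilinear <- function(x, out_hw) {
  vx <- ad_value(x)
  d <- dim(vx)
  out <- .cpp_resize_bilinear_fwd(vx, as.integer(out_hw[1L]),
                                  as.integer(out_hw[2L]))
  if (!tracking(x)) return(out)
  new_node(out, function(g) {
    accum_grad(x, .cpp_resize_bilinear_bwd(g, d[1L], d[2L]))
  })
}

# rois: n x 4 in continuous feature-grid index coordinates.
ad_roi_align <- function(x, rois, out_size) {
  vx <- ad_value(x)
  d <- dim(vx)
  out <- .cpp_roi_align_fwd(vx, rois, as.integer(out_size))
  if (!tracking(x)) return(out)
  new_node(out, function(g) {
    accum_grad(x, .cpp_roi_align_bwd(g, rois, d[1L], d[2L]))
  })
}

# ---- pairwise affinity for the non-local positional term ------------------

# theta, phi: N x C matrices (rows = positions). Returns the length-N
# vector a with a_i = mean over j != i of <theta_j, phi_i>, computed as
# ((sum_j theta_j) . phi_i - theta_i . phi_i) / (N - 1). N = 1 gives 0.
ad_local_affinity <- function(theta, phi) {
  vt <- ad_value(theta); vp <- ad_value(phi)
  n <- nrow(vt)
  if (n == 1L) {
    out <- 0
    if (!tracking(theta, phi)) return(out)
    return(new_node(out, function(g) NULL))
  }
  s <- colSums(vt)
  out <- (as.vector(vp %*% s) - rowSums(vt * vp)) / (n - 1)
  if (!tracking(theta, phi)) return(out)
  new_node(out, function(g) {
    g <- as.vector(g)
    # d a_i / d theta_j = phi_i / (n-1) for j != i
    gp <- colSums(g * vp)                       # sum_i g_i phi_i  (length C)
    dtheta <- (matrix(gp, n, length(gp), byrow = TRUE) - g * vp) / (n - 1)
    dphi <- g * (matrix(s, n, length(s), byrow = TRUE) - vt) / (n - 1)
    accum_grad(theta, dtheta)
    accum_grad(phi, dphi)
  })
}

# a: length-n vector of per-row scalars; M: n x C matrix. Row-wise scaling.
ad_mul_rows <- function(a, M) {
  va <- ad_value(a); vM <- ad_value(M)
  out <- vM * va  # column-major recycling scales row i by a_i
  if (!tracking(a, M)) return(out)
  new_node(out, function(g) {
    accum_grad(M, g * va)
    accum_grad(a, rowSums(g * vM))
  })
}

# Multiply an array by a (possibly learnable) scalar.
ad_mul_scalar <- function(x, s) {
  vx <- ad_value(x); vs <- ad_value(s)
  out <- vx * vs
  if (!tracking(x, s)) return(out)
  new_node(out, function(g) {
    accum_grad(x, g * vs)
    accum_grad(s, sum(g * vx))
  })
}

# ---- losses ---------------------------------------------------------------

# logits: n x K; labels: integer vector in 1..K. Mean cross-entropy.
ad_softmax_ce <- function(logits, labels) {
  v <- ad_value(logits)
  n <- nrow(v)
  m <- v - apply(v, 1L, max)
  e <- exp(m)
  p <- e / rowSums(e)
  idx <- cbind(seq_len(n), labels)
  out <- -mean(log(pmax(p[idx], 1e-12)))
  if (!tracking(logits)) return(out)
  new_node(out, function(g) {
    d <- p
    d[idx] <- d[idx] - 1
    accum_grad(logits, g * d / n)
  })
}

# logits, targets: vectors; targets in {0,1}. Mean binary CE on logits.
ad_sigmoid_bce <- function(logits, targets) {
  v <- ad_value(logits)
  n <- length(v)
  # stable: log(1+exp(-|v|)) + max(v,0) - v*t
  out <- mean(pmax(v, 0) - v * targets + log1p(exp(-abs(v))))
  if (!tracking(logits)) return(out)
  p <- 1 / (1 + exp(-v))
  new_node(out, function(g) accum_grad(logits, g * (p - targets) / n))
}

# Mean absolute error; `norm` overrides the averaging denominator.
ad_l1_loss <- function(pred, target, norm = NULL) {
  v <- ad_value(pred)
  r <- v - target
  n <- if (is.null(norm)) length(r) else norm
  if (length(r) == 0L) return(ad_scale_scalar_zero(pred))
  out <- sum(abs(r)) / n
  if (!tracking(pred)) return(out)
  new_node(out, function(g) accum_grad(pred, g * sign(r) / n))
}

# Smooth L1 (Huber) with transition point `beta`; sum / norm.
ad_smooth_l1_loss <- function(pred, target, beta = 1, norm = NULL) {
  v <- ad_value(pred)
  r <- v - target
  n <- if (is.null(norm)) length(r) else norm
  if (length(r) == 0L) return(ad_scale_scalar_zero(pred))
  a <- abs(r)
  e <- ifelse(a < beta, 0.5 * r^2 / beta, a - 0.5 * beta)
  out <- sum(e) / n
  if (!tracking(pred)) return(out)
  new_node(out, function(g) {
    d <- ifelse(a < beta, r / beta, sign(r))
    accum_grad(pred, g * d / n)
  })
}

ad_scale_scalar_zero <- function(x) {
  if (!tracking(x)) return(0)
  new_node(0, function(g) NULL)
}

# Weighted sum of scalar nodes/values.
ad_sum_scalars <- function(xs, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(xs))
  out <- sum(mapply(function(x, w) ad_value(x) * w, xs, weights))
  if (!ad_tape_active() || !any(vapply(xs, is_ad_node, logical(1)))) {
    return(out)
  }
  new_node(out, function(g) {
    for (k in seq_along(xs)) accum_grad(xs[[k]], g * weights[k])
  })
}
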