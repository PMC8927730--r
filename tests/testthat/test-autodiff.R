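# Reverse-mode gradients of the dense kernels, against central finite
# differences on small random instances.

`%||%` <- function(a, b) if (is.null(a)) b else a

fd_grad <- function(f, x, i, eps = 1e-6) {
  xp <- x; xp[i] <- xp[i] + eps
  xm <- x; xm[i] <- xm[i] - eps
  (f(xp) - f(xm)) / (2 * eps)
}

check_op <- function(fwd, args, wrt, n_checks = 6, tol = 1e-5) {
  grads <- with_tape({
    nodes <- lapply(args, ad_var)
    out <- fwd(nodes)
    # reduce to a scalar with fixed random weights for a stringent check
    ov <- ad_value(out)
    wts <- array(sin(seq_along(ov)), dim(ov) %||% length(ov))
    loss <- trapdetect:::new_node(
      sum(ad_value(out) * wts),
      function(g) trapdetect:::accum_grad(out, g * wts))
    ad_backward(loss)
    lapply(nodes, function(n) n$grad)
  })
  for (nm in wrt) {
    f_scalar <- function(z) {
      a2 <- args; a2[[nm]] <- z
      v <- ad_value(fwd(a2))
      sum(v * array(sin(seq_along(v)), dim(v) %||% length(v)))
    }
    idx <- sample(length(args[[nm]]), min(n_checks, length(args[[nm]])))
    for (i in idx) {
      expect_equal(grads[[nm]][i], fd_grad(f_scalar, args[[nm]], i),
                   tolerance = tol,
                   label = sprintf("analytic grad of %s[%d]", nm, i))
    }
  }
}

test_that("convolution forward/backward match finite differences", {
  set.seed(11)
  x <- array(rnorm(5 * 6 * 3), c(5, 6, 3))
  w <- array(rnorm(3 * 3 * 3 * 2, sd = 0.3), c(3, 3, 3, 2))
  b <- rnorm(2)
  check_op(function(n) trapdetect:::ad_conv2d(n$x, n$w, n$b, 2L, 1L),
           list(x = x, w = w, b = b), c("x", "w", "b"))
  check_op(function(n) trapdetect:::ad_conv2d(n$x, n$w, n$b, 1L, 1L),
           list(x = x, w = w, b = b), c("x", "w", "b"))
  w1 <- array(rnorm(3 * 2), c(1, 1, 3, 2))
  check_op(function(n) trapdetect:::ad_conv2d(n$x, n$w, n$b, 1L, 0L),
           list(x = x, w = w1, b = b), c("x", "w", "b"))
})

test_that("transposed convolution doubles size and matches finite diffs", {
  set.seed(12)
  x <- array(rnorm(4 * 5 * 2), c(4, 5, 2))
  w <- array(rnorm(4 * 4 * 2 * 3, sd = 0.3), c(4, 4, 2, 3))
  b <- rnorm(3)
  y <- trapdetect:::.cpp_convt2d_fwd(x, w, b, 2L, 1L)
  expect_equal(dim(y), c(8L, 10L, 3L))
  check_op(function(n) trapdetect:::ad_conv_transpose2d(n$x, n$w, n$b),
           list(x = x, w = w, b = b), c("x", "w", "b"))
})

test_that("bilinear resize is exact on constants and differentiable", {
  set.seed(13)
  x <- array(rnorm(6 * 7 * 2), c(6, 7, 2))
  const <- array(3.5, c(6, 7, 1))
  up <- trapdetect:::.cpp_resize_bilinear_fwd(const, 12L, 14L)
  expect_equal(as.vector(up), rep(3.5, 12 * 14))
  check_op(function(n) trapdetect:::ad_resize_bilinear(n$x, c(11, 4)),
           list(x = x), "x")
})

test_that("RoIAlign matches a dense bilinear sampling oracle", {
  set.seed(14)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  roi <- matrix(c(1.2, 0.8, 6.4, 5.9), 1)  # grid index coords
  out <- trapdetect:::.cpp_roi_align_fwd(x, roi, 3L)
  expect_equal(dim(out), c(3L, 3L, 2L, 1L))
  # oracle: average of the same 2x2 sample points, sampled bilinearly
  bilin <- function(ch, yy, xx) {
    y0 <- floor(min(max(yy, 0), 7)); x0 <- floor(min(max(xx, 0), 7))
    y0 <- min(y0, 7); x0 <- min(x0, 7)
    y1 <- min(y0 + 1, 7); x1 <- min(x0 + 1, 7)
    wy <- min(max(yy, 0), 7) - y0; wx <- min(max(xx, 0), 7) - x0
    (1 - wy) * ((1 - wx) * x[y0 + 1, x0 + 1, ch] + wx * x[y0 + 1, x1 + 1, ch]) +
      wy * ((1 - wx) * x[y1 + 1, x0 + 1, ch] + wx * x[y1 + 1, x1 + 1, ch])
  }
  bw <- (roi[3] - roi[1]) / 3; bh <- (roi[4] - roi[2]) / 3
  for (ch in 1:2) {
    for (bi in 0:2) {
      for (bj in 0:2) {
        acc <- 0
        for (sy in 0:1) for (sx in 0:1) {
          yy <- roi[2] + (bi + (sy + 0.5) / 2) * bh
          xx <- roi[1] + (bj + (sx + 0.5) / 2) * bw
          acc <- acc + bilin(ch, yy, xx)
        }
        expect_equal(out[bi + 1, bj + 1, ch, 1], acc / 4, tolerance = 1e-5)
      }
    }
  }
  check_op(function(n) trapdetect:::ad_roi_align(n$x, roi, 3L),
           list(x = x), "x")
})

test_that("constant feature maps pool to constant RoIAlign grids", {
  x <- array(2.25, c(10, 12, 3))
  fp <- feature_pyramid(list(feature_map(x, 4L)))
  # within the interior, every bilinear sample sees the constant
  out <- roi_pool(fp, matrix(c(8, 8, 30, 28), 1), output_size = 5,
                  finest_scale = 1e6)
  expect_equal(as.vector(out), rep(2.25, 5 * 5 * 3))
  expect_equal(dim(out), c(5L, 5L, 3L, 1L))
})

test_that("affinity, pooling and loss gradients match finite differences", {
  set.seed(15)
  th <- matrix(rnorm(12), 4, 3); ph <- matrix(rnorm(12), 4, 3)
  check_op(function(n) trapdetect:::ad_local_affinity(n$t, n$p),
           list(t = th, p = ph), c("t", "p"))
  x <- array(rnorm(3 * 4 * 2), c(3, 4, 2))
  check_op(function(n) trapdetect:::ad_gap(n$x), list(x = x), "x")
  check_op(function(n) trapdetect:::ad_gmp(n$x), list(x = x), "x")
  # loss closed forms: SmoothL1 at |x| = 0.5 is 0.125; L1 is 0.5
  expect_equal(trapdetect:::ad_smooth_l1_loss(0.5, 0, beta = 1), 0.125)
  expect_equal(trapdetect:::ad_l1_loss(0.5, 0), 0.5)
  expect_equal(trapdetect:::ad_smooth_l1_loss(2, 0, beta = 1), 1.5)
  # gradient of softmax CE
  logits <- matrix(rnorm(6), 2, 3)
  labels <- c(2L, 3L)
  g <- with_tape({
    n <- ad_var(logits)
    loss <- trapdetect:::ad_softmax_ce(n, labels)
    ad_backward(loss)
    n$grad
  })
  f <- function(z) {
    p <- exp(z - apply(z, 1, max)); p <- p / rowSums(p)
    -mean(log(p[cbind(1:2, labels)]))
  }
  for (i in 1:6) expect_equal(g[i], fd_grad(f, logits, i), tolerance = 1e-5)
})
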