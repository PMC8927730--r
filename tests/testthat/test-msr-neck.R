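# MSR neck: super-resolution expansion, full fusion, full weighting.

tiny_pyramid <- function(seed = 3, hw = c(64L, 64L),
                         channels = c(8L, 16L, 32L, 64L)) {
  set.seed(seed)
  cfg <- backbone_config(stage_channels = channels, stem_channels = 8L)
  params <- init_backbone(cfg)
  img <- array(runif(prod(hw) * 3), c(hw, 3L))
  list(fp = extract_features(img, params, cfg), cfg = cfg)
}

test_that("sr_component expands 4 levels to 6 with doubling strides", {
  tp <- tiny_pyramid()
  set.seed(4)
  neck <- init_msr_neck(msr_config(out_channels = 16L),
                        in_channels = tp$cfg$stage_channels)
  sr <- sr_component(tp$fp, neck)
  expect_length(sr, 6L)
  expect_equal(attr(sr, "strides"), c(2L, 4L, 8L, 16L, 32L, 64L))
  for (l in sr) expect_equal(dim(l)[3L], 16L)
  expect_equal(dim(sr[[1L]])[1:2], c(32L, 32L))  # deconvolved stride-2
  expect_equal(dim(sr[[6L]])[1:2], c(1L, 1L))    # pooled stride-64
  # zero-initialized weights give an all-zero pyramid (linearity)
  zneck <- neck
  zneck$params[c("lateral", "deconv", "smooth")] <-
    trapdetect:::zero_like(neck$params[c("lateral", "deconv", "smooth")])
  zsr <- sr_component(tp$fp, zneck)
  for (l in zsr) expect_equal(max(abs(l)), 0)
  expect_error(sr_component(feature_pyramid(tp$fp[1:3]), neck), "4-level")
})

test_that("full_fusion with zero fusion weights is the residual identity", {
  tp <- tiny_pyramid()
  set.seed(5)
  neck <- init_msr_neck(msr_config(out_channels = 16L),
                        in_channels = tp$cfg$stage_channels)
  sr <- sr_component(tp$fp, neck)
  zneck <- neck
  zneck$params$fusion <- trapdetect:::zero_like(neck$params$fusion)
  ff <- full_fusion(sr, zneck)
  expect_length(ff, 5L)
  expect_equal(attr(ff, "strides"), c(4L, 8L, 16L, 32L, 64L))
  for (t in 1:5) {
    expect_equal(unclass(ff[[t]]), unclass(sr[[t + 1L]]),
                 ignore_attr = TRUE)
  }
  # with non-zero weights the pre-projection stack is 6x the width
  expect_equal(dim(neck$params$fusion[[1L]]$w)[3L], 6L * 16L)
})

test_that("local term matches the brute-force double loop", {
  # frozen closed form: 2x2 map, values 1..4, identity maps; position i
  # gets (mean over other positions of x_j * x_i) * x_i
  X <- array(c(1, 2, 3, 4), c(2, 2, 1))
  wp <- full_weighting_params(1L)
  lt <- local_term(X, wp)
  expect_equal(as.vector(lt), c(3, 32 / 3, 21, 32))
  expect_equal(lt, oracle_local_term(X, wp$theta_L, wp$phi_L, wp$g))
  # single position: empty sum is zero
  expect_equal(as.vector(local_term(array(5, c(1, 1, 1)), wp)), 0)
  # random maps on a 5x7x3 grid
  set.seed(21)
  X <- array(rnorm(5 * 7 * 3), c(5, 7, 3))
  wp <- full_weighting_params(
    3L,
    theta_L = list(w = matrix(rnorm(9), 3), b = rnorm(3)),
    phi_L = list(w = matrix(rnorm(9), 3), b = rnorm(3)),
    g = list(w = matrix(rnorm(9), 3), b = rnorm(3)))
  expect_equal(local_term(X, wp),
               oracle_local_term(X, wp$theta_L, wp$phi_L, wp$g),
               tolerance = 1e-10)
  expect_error(local_term(array(0, c(2, 2, 4)), wp), "channel mismatch")
})

test_that("channel term pools, rectifies and ignores position order", {
  X <- array(rep(c(1, 3), each = 4), c(2, 2, 2))
  expect_equal(channel_term(X, full_weighting_params(2L)), c(2, 6))
  # channel maps forced negative: rectifier zeroes the weights
  neg <- full_weighting_params(
    2L,
    theta_C = list(w = matrix(0, 2, 2), b = c(-1, -1)),
    phi_C = list(w = matrix(0, 2, 2), b = c(-2, -2)))
  expect_equal(channel_term(X, neg), c(0, 0))
  set.seed(22)
  X <- array(rnorm(3 * 4 * 2), c(3, 4, 2))
  wp <- full_weighting_params(2L)
  w1 <- channel_term(X, wp)
  perm <- sample(12)
  Xp <- array(matrix(X, 12, 2)[perm, ], c(3, 4, 2))
  expect_equal(channel_term(Xp, wp), w1)
})

test_that("full weighting obeys its mixture limits and composition", {
  X <- array(c(1, 2, 3, 4), c(2, 2, 1))
  wp <- full_weighting_params(1L)
  lt <- local_term(X, wp)
  cw <- channel_term(X, wp)   # ReLU(2.5) + ReLU(4) = 6.5
  expect_equal(cw, 6.5)
  expect_equal(full_weighting(X, wp, alpha = 1), lt)
  expect_equal(full_weighting(X, wp, alpha = 0), X * 6.5)
  expect_equal(as.vector(full_weighting(X, wp, alpha = 0.5)),
               0.5 * c(3, 32 / 3, 21, 32) + 0.5 * 6.5 * c(1, 2, 3, 4))
  set.seed(23)
  X <- array(rnorm(4 * 5 * 3), c(4, 5, 3))
  wp <- full_weighting_params(3L)
  expect_equal(full_weighting(X, wp, alpha = 0),
               X * rep(channel_term(X, wp), each = 20))
  expect_equal(full_weighting(X, wp, alpha = 1), local_term(X, wp))
})

test_that("msr_forward meets the 5-level contract and is differentiable", {
  tp <- tiny_pyramid()
  set.seed(6)
  neck <- init_msr_neck(msr_config(out_channels = 16L),
                        in_channels = tp$cfg$stage_channels)
  out1 <- msr_forward(tp$fp, neck)
  out2 <- msr_forward(tp$fp, neck)
  expect_identical(out1, out2)
  expect_length(out1, 5L)
  expect_equal(attr(out1, "strides"), c(4L, 8L, 16L, 32L, 64L))
  for (l in out1) expect_equal(dim(l)[3L], 16L)
  # gradient reaches every learnable parameter from a scalar loss
  pyr <- trapdetect:::fp_to_internal(tp$fp)
  grads <- with_tape({
    pn <- trapdetect:::wrap_params(neck$params)
    res <- trapdetect:::msr_forward_core(pn, neck$config, pyr)
    loss_val <- sum(vapply(res, function(l) sum(ad_value(l$x)^2),
                           numeric(1)))
    loss <- trapdetect:::new_node(loss_val, function(g) {
      for (l in res) trapdetect:::accum_grad(l$x, g * 2 * ad_value(l$x))
    })
    ad_backward(loss)
    trapdetect:::collect_grads(pn)
  })
  flat <- unlist(grads)
  expect_true(all(is.finite(flat)))
  leaf_norms <- leaf_abs_sums(grads)
  expect_true(all(leaf_norms > 0))
})

test_that("msr and fpn necks are interchangeable downstream", {
  tp <- tiny_pyramid()
  set.seed(8)
  cfgm <- msr_config(out_channels = 16L)
  msr <- init_msr_neck(cfgm, in_channels = tp$cfg$stage_channels)
  fpn <- init_fpn_neck(cfgm, in_channels = tp$cfg$stage_channels)
  om <- msr_forward(tp$fp, msr)
  of <- fpn_forward(tp$fp, fpn)
  expect_equal(lapply(om, dim), lapply(of, dim))
  expect_equal(attr(om, "strides"), attr(of, "strides"))
})
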