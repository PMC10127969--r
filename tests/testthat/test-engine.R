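# The differentiation engine: kernels against brute-force oracles and
# finite-difference gradient checks.

test_that("convolution matches the nested-loop oracle on 5x5 inputs", {
  set.seed(11)
  for (k in c(1L, 3L)) {
    for (d in if (k == 1L) 1L else c(1L, 2L, 4L)) {
      x <- rand_chwn(2, 5, 5)
      w <- array(rnorm(3 * 2 * k * k), c(3, 2, k, k))
      b <- rnorm(3)
      got <- eng$cpp_conv2d_fw(x, w, b, d)
      expect_lt(max(abs(got - naive_conv2d(x, w, b, d))), 1e-5)
    }
  }
})

test_that("an all-ones 3x3 kernel on an all-ones 5x5 input gives 9 at the center", {
  x <- array(1, c(1, 5, 5, 1))
  w <- array(1, c(1, 1, 3, 3))
  out <- eng$cpp_conv2d_fw(x, w, 0, 1L)
  expect_equal(out[1, 3, 3, 1], 9, tolerance = 1e-6)
  expect_equal(out[1, 1, 1, 1], 4, tolerance = 1e-6)  # zero padding at the corner
})

test_that("dilated convolution spans k + (k-1)(d-1) pixels", {
  # impulse response support of a 3x3 kernel at dilation 4 is a 9x9 grid
  x <- array(0, c(1, 21, 21, 1))
  x[1, 11, 11, 1] <- 1
  w <- array(1, c(1, 1, 3, 3))
  out <- eng$cpp_conv2d_fw(x, w, 0, 4L)
  nz <- which(out[1, , , 1] != 0, arr.ind = TRUE)
  expect_equal(sort(unique(nz[, 1])), c(7, 11, 15))
  expect_equal(diff(range(nz[, 1])) + 1, 3 + 2 * 3)  # 9-pixel span
})

test_that("stride-1 window-3 max pooling equals the window-max oracle", {
  set.seed(12)
  x <- rand_chwn(1, 4, 4)
  got <- eng$cpp_maxpool_fw(x, 3L, 1L, 1L)$out
  expect_equal(got, naive_maxpool3(x))
  # 4x4 ramp case: every output is the max of its 3x3 neighbourhood
  ramp <- array(seq_len(16), c(1, 4, 4, 1))
  expect_equal(eng$cpp_maxpool_fw(ramp, 3L, 1L, 1L)$out,
               naive_maxpool3(ramp))
})

test_that("bilinear x2 of a constant map is constant and doubles dims", {
  x <- array(3.7, c(2, 8, 6, 1))
  up <- eng$cpp_resize_bilinear(x, 16L, 12L)
  expect_equal(dim(up), c(2L, 16L, 12L, 1L))
  expect_equal(range(up), c(3.7, 3.7))
  # applying twice quadruples H and W
  up2 <- eng$cpp_resize_bilinear(up, 32L, 24L)
  expect_equal(dim(up2)[2:3], c(32L, 24L))
})

test_that("average pooling halves dims and averages 2x2 cells", {
  x <- array(0, c(1, 2, 2, 1))
  x[1, , , 1] <- matrix(c(1, 2, 3, 4), 2)
  out <- eng$cpp_avgpool2_fw(x)
  expect_equal(dim(out), c(1L, 1L, 1L, 1L))
  expect_equal(out[1, 1, 1, 1], 2.5)
})

test_that("backward pass matches central finite differences through PRM", {
  set.seed(13)
  blk <- prmBlock(4L)
  ps <- eng$module_params(blk)
  x <- rand_chwn(4, 6, 6)
  tgt <- array(rbinom(36, 1, 0.5), c(1, 6, 6, 1))
  ones <- list(val = matrix(1, 4, 1))
  eval_loss <- function() {
    eng$ag_begin(grad = FALSE)
    on.exit(eng$ag_end(), add = TRUE)
    out <- eng$mod_forward(blk, eng$nd_input(x), TRUE)
    s <- eng$op_chan_weighted_sum(out, ones)
    eng$op_bce_dice(s, tgt)$val
  }
  eng$ag_begin(grad = TRUE)
  out <- eng$mod_forward(blk, eng$nd_input(x), TRUE)
  l <- eng$op_bce_dice(eng$op_chan_weighted_sum(out, ones), tgt)
  eng$backward(l)
  eng$ag_end()
  for (nm in c("pool_conv.w", "pre_dw.gamma", "dw.w", "fuse.w", "fuse.beta")) {
    p <- ps[[nm]]
    i <- which.max(abs(p$grad))
    g_analytic <- p$grad[i]
    eps <- 1e-4
    v0 <- p$val
    p$val[i] <- v0[i] + eps
    lp <- eval_loss()
    p$val[i] <- v0[i] - eps
    lm <- eval_loss()
    p$val <- v0
    fd <- (lp - lm) / (2 * eps)
    expect_equal(g_analytic, fd, tolerance = 2e-2)
  }
})

test_that("max/avg pooling and upsampling gradients scatter correctly", {
  # maxpool routes the gradient to the argmax position only
  x <- array(0, c(1, 2, 2, 1))
  x[1, , , 1] <- matrix(c(1, 5, 2, 3), 2)
  r <- eng$cpp_maxpool_fw(x, 2L, 2L, 0L)
  g <- array(1, c(1, 1, 1, 1))
  gx <- eng$cpp_maxpool_bw(g, r$argmax, dim(x))
  expect_equal(as.vector(gx), c(0, 1, 0, 0))
  # avgpool spreads it uniformly
  gxa <- eng$cpp_avgpool2_bw(g, dim(x))
  expect_equal(as.vector(gxa), rep(0.25, 4))
  # bilinear-x2 backward conserves total mass
  set.seed(14)
  go <- rand_chwn(1, 8, 8)
  gxb <- eng$cpp_resize_bilinear_bw(go, c(1L, 4L, 4L, 1L))
  expect_equal(sum(gxb), sum(go), tolerance = 1e-10)
})
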