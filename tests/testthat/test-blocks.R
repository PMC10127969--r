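# Behaviour of the individual network blocks.

test_that("convUnit preserves spatial dims and maps channels", {
  set.seed(21)
  blk <- convUnit(3L, 16L, 3L)
  x <- array(rnorm(3 * 32 * 32), c(1, 3, 32, 32))
  expect_equal(dim(blockForward(blk, x)), c(1L, 16L, 32L, 32L))
  dil <- convUnit(4L, 4L, 3L, dilation = 4L)
  xd <- array(rnorm(4 * 24 * 24), c(1, 4, 24, 24))
  expect_equal(dim(blockForward(dil, xd)), c(1L, 4L, 24L, 24L))
})

test_that("convUnit reports a channel mismatch naming expected and received", {
  set.seed(21)
  blk <- convUnit(3L, 8L, 3L)
  x <- array(rnorm(5 * 8 * 8), c(1, 5, 8, 8))
  expect_error(blockForward(blk, x), "expected 3 .*received 5")
})

test_that("residual blocks preserve shape for randomized sizes", {
  set.seed(22)
  for (hw in c(16L, 32L, 64L)) {
    C <- sample(c(4L, 8L, 16L), 1)
    x <- array(rnorm(C * hw * hw * 2), c(2, C, hw, hw))
    expect_equal(dim(blockForward(prmBlock(C), x)), dim(x))
    expect_equal(dim(blockForward(samBlock(C), x)), dim(x))
  }
})

test_that("PRM and SAM with all-zero weights are exact identities", {
  set.seed(23)
  x <- array(rnorm(8 * 16 * 16), c(1, 8, 16, 16))
  prm <- zeroWeights(prmBlock(8L))
  expect_equal(max(abs(blockForward(prm, x) - x)), 0)
  sam <- zeroWeights(samBlock(8L))
  expect_equal(max(abs(blockForward(sam, x) - x)), 0)
})

test_that("PRM rejects non-finite input at entry", {
  set.seed(23)
  blk <- prmBlock(4L)
  x <- array(rnorm(4 * 16 * 16), c(1, 4, 16, 16))
  x[1, 1, 1, 1] <- NaN
  expect_error(blockForward(blk, x), "non-finite")
})

test_that("SE gates are 0.5 with zeroed weights and the hand case evaluates", {
  set.seed(24)
  x <- array(rnorm(8 * 10 * 10), c(1, 8, 10, 10))
  se <- zeroWeights(seBlock(8L))
  expect_equal(blockForward(se, x), 0.5 * x, tolerance = 1e-12)
  # 2-channel 1x1 input (4, 0) with an identity-like gate path, evaluated by
  # scalar arithmetic: squeeze = (4, 0); w1 = I, w2 = I (reduction 1);
  # gates = sigmoid(relu(4, 0)) = (0.9820138, 0.5)
  se2 <- seBlock(2L, reduction = 1L)
  ps <- eng$module_params(se2)
  ps$w1$val <- diag(2); ps$b1$val <- c(0, 0)
  ps$w2$val <- diag(2); ps$b2$val <- c(0, 0)
  x2 <- array(c(4, 0), c(1, 2, 1, 1))
  out <- blockForward(se2, x2)
  expect_equal(as.vector(out), c(4 * plogis(4), 0), tolerance = 1e-12)
  expect_error(seBlock(4L, reduction = 8L), "reduction")
})

test_that("SAM attention sums to one and V drives the context map", {
  set.seed(25)
  sam <- samBlock(16L)
  x <- array(rnorm(16 * 12 * 12 * 3), c(3, 16, 12, 12))
  a <- samAttention(sam, x)
  expect_equal(dim(a), c(3L, 16L))
  expect_true(all(abs(rowSums(a) - 1) < 1e-6))
  # V identically 1 => context map identically 1 regardless of attention
  ps <- eng$module_params(sam)
  ps$wv$val <- ps$wv$val * 0
  ps$bv$val <- rep(1, 16)
  out <- blockForward(sam, x)
  expect_equal(out - x, array(1, dim(x)), tolerance = 1e-12)
  # zero V projection => pure residual
  ps$bv$val <- rep(0, 16)
  expect_equal(blockForward(sam, x), x, tolerance = 1e-12)
})

test_that("dilated blocks use the multi-grid rates and keep shape", {
  cfg <- mbsnetConfig()
  expect_equal(dilationRates(cfg), c(2L, 4L, 8L))
  expect_equal(dilationRates(cfg)[3], 8L)  # block 3 uses rate 8
  set.seed(26)
  blk <- dilatedBlock(16L, 32L, 8L)
  x <- array(rnorm(16 * 32 * 32), c(1, 16, 32, 32))
  expect_equal(dim(blockForward(blk, x)), c(1L, 32L, 32L, 32L))
  expect_error(dilatedBlock(8L, 8L, 0L), "rate")
})

test_that("upconv doubles the spatial dims and preserves constants", {
  set.seed(27)
  up <- upconvBlock(8L, 4L)
  x <- array(rnorm(8 * 10 * 10), c(1, 8, 10, 10))
  expect_equal(dim(blockForward(up, x)), c(1L, 4L, 20L, 20L))
  # twice => x4
  up2 <- upconvBlock(4L, 4L)
  expect_equal(dim(blockForward(up2, blockForward(up, x))), c(1L, 4L, 40L, 40L))
})

test_that("FCFB cross-fuses: zero crossing conv leaves the projected upsample", {
  set.seed(28)
  blk <- fcfbBlock(8L, 4L)
  yg <- array(rnorm(8 * 10 * 10), c(1, 8, 10, 10))
  yl <- array(rnorm(8 * 10 * 10), c(1, 8, 10, 10))
  out <- fcfbForward(blk, yg, yl)
  expect_equal(dim(out$g), c(1L, 4L, 20L, 20L))
  expect_equal(dim(out$l), c(1L, 4L, 20L, 20L))
  # zero the crossing (upconv) weights: O_G must equal the projected upsample
  # of y_g alone
  ch <- eng$module_params(blk)
  for (nm in grep("^up_", names(ch), value = TRUE)) ch[[nm]]$val <- ch[[nm]]$val * 0
  out0 <- fcfbForward(blk, yg, yl)
  proj <- run_block(blk$children$proj_g, eng$as_internal(yg))
  expect_equal(out0$g, eng$as_public(proj), tolerance = 1e-12)
  expect_error(fcfbForward(blk, yg, array(0, c(1, 8, 5, 5))), "identical shapes")
})

test_that("every learnable tensor receives gradient somewhere in every block", {
  set.seed(29)
  blocks <- list(conv = convUnit(3L, 4L, 3L), prm = prmBlock(3L),
                 se = seBlock(4L, 2L), sam = samBlock(3L),
                 dil = dilatedBlock(3L, 4L, 2L), up = upconvBlock(3L, 2L))
  for (nm in names(blocks)) {
    blk <- blocks[[nm]]
    ci <- if (nm %in% c("se")) 4L else 3L
    x <- rand_chwn(ci, 8, 8, 2)
    ones <- list(val = matrix(1, dim(run_block(blk, x))[1], 2))
    eng$ag_begin(grad = TRUE)
    out <- eng$mod_forward(blk, eng$nd_input(x), TRUE)
    tgt <- array(rbinom(length(out$val) / dim(out$val)[1], 1, 0.5),
                 c(1, dim(out$val)[2:4]))
    s <- eng$op_chan_weighted_sum(out, ones)
    l <- eng$op_bce_dice(s, tgt)
    eng$backward(l)
    eng$ag_end()
    for (pn in names(eng$module_params(blk))) {
      p <- eng$module_params(blk)[[pn]]
      expect_false(is.null(p$grad), label = sprintf("%s/%s has grad", nm, pn))
      expect_gt(max(abs(p$grad)), 0, label = sprintf("%s/%s nonzero", nm, pn))
    }
  }
})
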