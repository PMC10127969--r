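# Network assembly, forward contracts, complexity accounting, checkpoints.

small_cfg <- function(...) mbsnetConfig(inputSize = c(64L, 64L), seed = 7L, ...)

test_that("configuration validity is enforced", {
  expect_error(mbsnetConfig(lChannels = c(16L, 8L, 64L, 128L, 256L)),
               "strictly increasing")
  expect_error(mbsnetConfig(inputSize = c(100L, 100L)), "divisible by 16")
  expect_error(mbsnetConfig(useBranchL = FALSE, useBranchG = FALSE),
               "at least one")
  expect_equal(dilationRates(mbsnetConfig(rateMultiplier = 3L)), c(3L, 6L, 12L))
})

test_that("forward is fully convolutional with a single logit channel", {
  net <- buildMBSNet(small_cfg())
  x64 <- array(runif(2 * 3 * 64 * 64), c(2, 3, 64, 64))
  y <- forward(net, x64)
  expect_equal(dim(y), c(2L, 1L, 64L, 64L))
  x128 <- array(runif(1 * 3 * 128 * 128), c(1, 3, 128, 128))
  expect_equal(dim(forward(net, x128)), c(1L, 1L, 128L, 128L))
  expect_error(forward(net, array(0, c(1, 4, 64, 64))), "shape")
  expect_error(forward(net, array(0, c(1, 3, 60, 60))), "divisible")
})

test_that("inference is deterministic for fixed weights", {
  net <- buildMBSNet(small_cfg())
  x <- array(runif(3 * 64 * 64), c(1, 3, 64, 64))
  expect_identical(forward(net, x), forward(net, x))
})

test_that("parameter count is a pure function of the configuration", {
  n1 <- buildMBSNet(small_cfg())
  n2 <- buildMBSNet(small_cfg())
  expect_identical(countParameters(n1), countParameters(n2))
  # identical seeds give identical weights too
  p1 <- eng$net_params(n1)
  p2 <- eng$net_params(n2)
  expect_identical(lapply(p1, function(p) p$val), lapply(p2, function(p) p$val))
})

test_that("a lone 3->16 k3 conv has 448 parameters and the printed MAC count", {
  blk <- convUnit(3L, 16L, 3L, norm = FALSE, activation = "none")
  np <- sum(vapply(eng$module_params(blk), function(p) length(p$val), numeric(1)))
  expect_equal(np, 3 * 3 * 3 * 16 + 16)
  # MAC formula at 320x320: 16 * 320 * 320 * 27
  th <- eng$the
  th$macs <- new.env()
  th$macs$total <- 0
  run_block(blk, array(0, c(3, 320, 320, 1)))
  macs <- th$macs$total
  th$macs <- NULL
  expect_equal(macs, 44236800)
})

test_that("component toggles strictly increase parameters and MACs", {
  steps <- list(
    dilated = small_cfg(usePRM = FALSE, useSE = FALSE, useSAM = FALSE),
    prm = small_cfg(useSE = FALSE, useSAM = FALSE),
    se = small_cfg(useSAM = FALSE),
    sab = small_cfg()
  )
  params <- vapply(steps, function(cf) countParameters(buildMBSNet(cf)), numeric(1))
  macs <- vapply(steps, function(cf) countMACs(buildMBSNet(cf), c(160L, 160L)),
                 numeric(1))
  expect_true(all(diff(params) > 0))
  expect_true(all(diff(macs) > 0))
  # disabling dilation keeps parameters but reduces nothing (same tensors)
  nd <- small_cfg(useDilated = FALSE)
  expect_equal(countParameters(buildMBSNet(nd)), params[["sab"]])
})

test_that("conv MACs scale by 4 when both spatial dims double", {
  cfg <- small_cfg(useSE = FALSE, useSAM = FALSE)  # conv layers only
  net <- buildMBSNet(cfg)
  expect_equal(countMACs(net, c(128L, 128L)) / countMACs(net, c(64L, 64L)), 4)
})

test_that("ablation branch modes build and keep the output contract", {
  x <- array(runif(3 * 64 * 64), c(1, 3, 64, 64))
  for (cfg in list(small_cfg(useBranchG = FALSE),      # plain encoder-decoder
                   small_cfg(useBranchL = FALSE),      # G only
                   small_cfg(useFCFB = FALSE))) {      # L+G without FCFB
    net <- buildMBSNet(cfg)
    expect_equal(dim(forward(net, x)), c(1L, 1L, 64L, 64L))
  }
  # full network instantiates 5 PRM, 5 SE and 1 SAM module
  full <- buildMBSNet(small_cfg())
  types <- vapply(full@state$mods, function(m) m$type, character(1))
  expect_equal(sum(types == "prm"), 5L)
  expect_equal(sum(types == "se"), 5L)
  expect_equal(sum(types == "sam"), 1L)
})

test_that("checkpoints round-trip bit-exactly", {
  net <- buildMBSNet(small_cfg())
  # perturb away from init so the test is not trivial
  for (p in eng$net_params(net)) p$val <- p$val + runif(length(p$val), -0.1, 0.1)
  f <- tempfile(fileext = ".rds")
  saveCheckpoint(net, f)
  net2 <- loadCheckpoint(f)
  p1 <- lapply(eng$net_params(net), function(p) p$val)
  p2 <- lapply(eng$net_params(net2), function(p) p$val)
  expect_identical(p1, p2)
  x <- array(runif(3 * 64 * 64), c(1, 3, 64, 64))
  expect_identical(forward(net, x), forward(net2, x))
})
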