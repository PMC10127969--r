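# Joint loss and segmentation metrics.

test_that("bceDiceLoss reproduces the 4-pixel hand computation", {
  # target (1,1,0,0), p = 0.5 everywhere (logits 0), eps = 1:
  # BCE = log 2; Dice = 1 - (2*1 + 1)/(2 + 2 + 1) = 0.4; L = 0.5*log2 + 0.4
  logits <- array(0, c(1, 1, 2, 2))
  target <- array(c(1, 1, 0, 0), c(1, 1, 2, 2))
  expect_equal(bceDiceLoss(logits, target), 0.5 * log(2) + 0.4,
               tolerance = 1e-10)
  expect_equal(round(bceDiceLoss(logits, target), 5), 0.74657)
})

test_that("loss approaches zero for perfect predictions and rejects bad targets", {
  target <- array(c(1, 1, 0, 0), c(1, 1, 2, 2))
  logits <- array(ifelse(target == 1, 50, -50), dim(target))
  expect_lt(bceDiceLoss(logits, target), 1e-3)
  expect_gte(bceDiceLoss(logits * 0, target), 0)
  expect_error(bceDiceLoss(logits, target + 0.5), "binary")
})

test_that("loss is non-increasing as predictions move toward the target", {
  set.seed(31)
  for (rep in 1:20) {
    target <- array(rbinom(64, 1, 0.4), c(1, 1, 8, 8))
    z0 <- array(rnorm(64, sd = 2), dim(target))
    z1 <- array(ifelse(target == 1, 20, -20), dim(target))
    ts <- seq(0, 1, length.out = 11)
    ls <- vapply(ts, function(t) bceDiceLoss(z0 + t * (z1 - z0), target),
                 numeric(1))
    expect_true(all(diff(ls) <= 1e-8))
  }
})

test_that("binarize uses >= 0.5 with boundary mapping to foreground", {
  p <- array(c(0.5, 0.499, 0, 1), c(2, 2))
  expect_equal(as.vector(binarize(p)), c(1L, 0L, 0L, 1L))
  expect_equal(sum(binarize(array(0, c(4, 4)))), 0L)
})

test_that("confusion counts enumerate the 4-pixel case exactly", {
  cc <- confusionCounts(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(cc, list(TP = 1L, FP = 1L, TN = 1L, FN = 1L))
  gt <- matrix(rbinom(16, 1, 0.5), 4)
  expect_equal(confusionCounts(gt, gt)$FP + confusionCounts(gt, gt)$FN, 0L)
  inv <- 1 - gt
  expect_equal(confusionCounts(inv, gt)$TP + confusionCounts(inv, gt)$TN, 0L)
  expect_error(confusionCounts(c(1, 0), c(1, 0, 1)), "identical shapes")
})

test_that("metrics formulas give 33.33/50/50 on the balanced 4-pixel table", {
  m <- metricsFromCounts(list(TP = 1, FP = 1, TN = 1, FN = 1))
  expect_equal(m$IOU, 100 / 3, tolerance = 1e-10)
  expect_equal(m$F1, 50)
  expect_equal(m$Gmean, 50)
  perfect <- metricsFromCounts(list(TP = 7, FP = 0, TN = 9, FN = 0))
  expect_true(all(perfect[, c("IOU", "F1", "Gmean")] == 100))
  degen <- metricsFromCounts(list(TP = 0, FP = 3, TN = 5, FN = 2))
  expect_equal(degen$F1, 0)
  both_empty <- metricsFromCounts(list(TP = 0, FP = 0, TN = 10, FN = 0))
  expect_true(all(both_empty[, c("IOU", "F1", "Gmean")] == 100))
  expect_equal(both_empty$flag, "both-empty")
  empty_gt <- metricsFromCounts(list(TP = 0, FP = 4, TN = 6, FN = 0))
  expect_equal(empty_gt$IOU, 0)
  expect_equal(empty_gt$F1, 0)
})

test_that("metrics agree with a brute-force recount over 200 random pairs", {
  set.seed(32)
  for (i in 1:200) {
    pred <- matrix(rbinom(64, 1, runif(1)), 8)
    gt <- matrix(rbinom(64, 1, runif(1)), 8)
    cc <- confusionCounts(pred, gt)
    # independent recount straight from definitions
    tp <- sum(pred == 1 & gt == 1); fp <- sum(pred == 1 & gt == 0)
    fn <- sum(pred == 0 & gt == 1); tn <- sum(pred == 0 & gt == 0)
    expect_identical(unlist(cc), c(TP = tp, FP = fp, TN = tn, FN = fn))
    m <- metricsFromCounts(cc)
    if (tp + fp + fn > 0) {
      expect_equal(m$IOU, 100 * tp / (tp + fp + fn))
      expect_equal(m$F1, 100 * 2 * tp / (2 * tp + fp + fn), tolerance = 1e-10)
      # F1 dominates IOU (Dice >= Jaccard)
      expect_gte(m$F1 + 1e-9, m$IOU)
    }
    expect_true(all(m[, 1:6] >= 0 & m[, 1:6] <= 100))
  }
})

test_that("dataset evaluation macro-averages per-image metrics", {
  a <- matrix(1, 4, 4); z <- matrix(0, 4, 4)
  one <- evaluateDataset(list(a), list(a))
  expect_equal(one$IOU[one$image == "MEAN"], 100)
  # IOU 100 and IOU 0 average to 50
  two <- evaluateDataset(list(a, a), list(a, z))
  expect_equal(two$IOU[two$image == "MEAN"], 50)
  # duplicating the list leaves the mean unchanged
  four <- evaluateDataset(list(a, a, a, a), list(a, z, a, z))
  expect_equal(four$IOU[four$image == "MEAN"], 50)
  expect_error(evaluateDataset(list(), list()), "empty")
  # CSV round trip
  f <- tempfile(fileext = ".csv")
  writeMetricsCSV(two, f)
  back <- read.csv(f)
  expect_equal(nrow(back), 3)
  expect_equal(back$IOU[3], 50)
})
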