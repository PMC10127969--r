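# TOPSIS scoring and cross-dataset ranking.

test_that("dominated and dominating rows score exactly 0 and 1", {
  pub <- published_results()
  # UNet++ is worst on every criterion of the ISIC2018 table
  sc <- topsisScores(decisionMatrix(pub$ISIC2018[, 1:3]))
  expect_equal(sc$score[sc$model == "UNet++"], 0)
  # a row that is best on every criterion scores exactly 1
  sc2 <- topsisScores(decisionMatrix(pub$Kvasir[, 1:3]))
  expect_equal(sc2$score[sc2$model == "MBSNet"], 1)
  expect_true(all(sc$score >= 0 & sc$score <= 1))
})

test_that("scores are invariant to positive column scaling and row permutation", {
  set.seed(41)
  v <- matrix(runif(15, 50, 95), 5, 3,
              dimnames = list(paste0("m", 1:5), c("F1", "IOU", "Gmean")))
  base <- topsisScores(decisionMatrix(v))$score
  v2 <- v
  v2[, 2] <- v2[, 2] * 37.5
  expect_equal(topsisScores(decisionMatrix(v2))$score, base, tolerance = 1e-12)
  perm <- c(3, 1, 5, 2, 4)
  sp <- topsisScores(decisionMatrix(v[perm, ]))
  expect_equal(sp$score, base[perm], tolerance = 1e-12)
})

test_that("improving a single benefit entry never lowers a model's score", {
  set.seed(42)
  for (i in 1:20) {
    v <- matrix(runif(12, 10, 100), 4, 3)
    rownames(v) <- paste0("m", 1:4)
    s0 <- topsisScores(decisionMatrix(v))$score
    r <- sample(4, 1); cc <- sample(3, 1)
    v2 <- v
    v2[r, cc] <- v2[r, cc] * 1.25
    s1 <- topsisScores(decisionMatrix(v2))$score
    expect_gte(s1[r] - s0[r], -1e-12)
  }
})

test_that("single-criterion ranking equals the descending sort of the column", {
  v <- matrix(c(3, 9, 1, 7), 4, 1, dimnames = list(paste0("m", 1:4), "F1"))
  sc <- topsisScores(decisionMatrix(v))
  expect_equal(sc$rank, c(3L, 1L, 4L, 2L))
})

test_that("identical rows are flagged and scored 0.5", {
  v <- matrix(5, 3, 2, dimnames = list(paste0("m", 1:3), c("a", "b")))
  expect_warning(sc <- topsisScores(decisionMatrix(v)), "identical")
  expect_equal(sc$score, rep(0.5, 3))
})

test_that("competition ranking shares the smaller rank on ties", {
  expect_equal(rankFromScores(c(0.238, 0.150, 0, 0.332, 0.280)),
               c(3L, 4L, 5L, 1L, 2L))
  expect_equal(rankFromScores(c(0.9, 0.9, 0.1)), c(1L, 1L, 3L))
  expect_equal(sort(rankFromScores(runif(6))), 1:6)
})

test_that("ranks from the published TOPSIS columns average to the reported values", {
  pub <- published_results()
  ranks <- lapply(pub, function(m) setNames(rankFromScores(m[, "TOPSIS"]),
                                            rownames(m)))
  tab <- averageRankTable(ranks)
  expect_equal(tab["MBSNet", "Average"], 1.6)
  expect_equal(tab["UNet", "Average"], 3.2)
  expect_equal(tab["UNeXt", "Average"], 2.6)
  # identical ranks everywhere average to that rank
  same <- averageRankTable(list(a = c(x = 1, y = 2), b = c(x = 1, y = 2)))
  expect_equal(same["x", "Average"], 1)
  expect_error(averageRankTable(list(a = c(x = 1), b = c(y = 1))), "differ")
})

test_that("decision matrices validate and round-trip through CSV", {
  expect_error(decisionMatrix(matrix(1, 1, 2)), "2 models")
  expect_error(decisionMatrix(matrix(c(1, 2, 0, 0), 2, 2)), "all-zero")
  expect_error(decisionMatrix(matrix(1:4, 2), weights = c(0.9, 0.5)), "sum to 1")
  f <- tempfile(fileext = ".csv")
  pub <- published_results()$BUSI[, 1:3]
  write.csv(data.frame(model = rownames(pub), pub, check.names = FALSE), f,
            row.names = FALSE)
  dm <- readDecisionMatrixCSV(f)
  expect_equal(dm@values, pub)
  expect_equal(topsisScores(dm)$rank[5], 1L)  # MBSNet best on BUSI
})
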