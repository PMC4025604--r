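test_that("AUC matches the rank formula on canonical cases", {
  expect_equal(aucScore(c(1, 2, 3, 4), c(-1, -1, 1, 1)), 1)
  expect_equal(aucScore(c(4, 3, 2, 1), c(-1, -1, 1, 1)), 0)
  expect_equal(aucScore(c(1, 2, 3, 4), c(-1, 1, -1, 1)), 0.75)
  expect_equal(aucScore(c(1, 1, 2, 2), c(-1, 1, -1, 1)), 0.5)  # ties -> 1/2
  expect_error(aucScore(1:3, c(1, 1, 1)), "both classes")
})

test_that("rank AUC equals brute-force pair counting on exhaustive labelings", {
  set.seed(80)
  for (n in 3:6) {
    scoreValues <- sample(1:4, n, replace = TRUE)  # forces ties
    for (mask in 1:(2^n - 2)) {
      y <- ifelse(bitwAnd(mask, 2^(0:(n - 1))) > 0, 1, -1)
      expect_equal(aucScore(scoreValues, y), bruteForceAUC(scoreValues, y))
    }
  }
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(81)
  v <- rnorm(40)
  y <- rep(c(-1, 1), 20)
  expect_equal(aucScore(v, y),
               as.numeric(pROC::auc(pROC::roc(y, v, quiet = TRUE,
                                              levels = c("-1", "1"),
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("signed-rank test is exact for small tie-free samples", {
  res <- signedRankTest(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1))
  expect_equal(res$p.value, 0.0625)  # 2 * 1/2^5
  expect_identical(res$method, "exact")
  expect_warning(res0 <- signedRankTest(1:5, 1:5), "zero")
  expect_equal(res0$p.value, 1)
})

test_that("signed-rank agrees with the reference implementation", {
  set.seed(82)
  for (i in 1:5) {
    a <- rnorm(12)
    b <- rnorm(12)
    ours <- signedRankTest(a, b)
    ref <- wilcox.test(a, b, paired = TRUE, exact = TRUE, correct = TRUE)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("exact and normal-approximation p values agree near n = 25", {
  set.seed(83)
  for (i in 1:5) {
    a <- rnorm(25)
    b <- rnorm(25)
    exact <- signedRankTest(a, b)
    expect_identical(exact$method, "exact")
    # force the approximation path by the same statistic
    d <- a - b
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    n <- 25
    mu <- n * (n + 1) / 4
    sig2 <- n * (n + 1) * (2 * n + 1) / 24
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    approx <- min(2 * pnorm(-abs(z)), 1)
    expect_lt(abs(exact$p.value - approx), 0.02)
  }
})

test_that("the repeated-split protocol is deterministic and leak-free", {
  d <- generateDataset(syntheticSpec(nPerClass = 12, d = 30,
                                     structure = "linear-shift", effect = 3,
                                     noiseSd = 0.5, seed = 90))
  r1 <- runProtocol(d, "whole", repeats = 3, seed = 17, tuneFolds = 4)
  r2 <- runProtocol(d, "whole", repeats = 3, seed = 17, tuneFolds = 4)
  expect_identical(repeatResults(r1), repeatResults(r2))
  expect_equal(r1@meanAUC, mean(r1@auc), tolerance = 1e-12)

  # taint check: decision values never depend on test labels
  plan <- stratifiedSplit(d, 2 / 3, seed = 3)
  std <- standardizeDataset(d, plan@trainIdx)
  train <- std[plan@trainIdx]
  testX <- exprMatrix(std)[plan@testIdx, ]
  model <- fitLinearPCA(train, 4)
  trainZ <- projectDataset(model, train)
  clf <- fitLSSVM(trainZ, spec = linearKernel(), gamma = 1)
  v1 <- decisionValues(clf, scores(model, testX))
  yCorrupt <- classLabels(d)
  yCorrupt[plan@testIdx] <- -yCorrupt[plan@testIdx]
  dCorrupt <- expressionDataset(exprMatrix(d), yCorrupt)
  stdC <- standardizeDataset(dCorrupt, plan@trainIdx)
  trainC <- stdC[plan@trainIdx]
  modelC <- fitLinearPCA(trainC, 4)
  clfC <- fitLSSVM(projectDataset(modelC, trainC),
                   spec = linearKernel(), gamma = 1)
  v2 <- decisionValues(clfC, scores(modelC, exprMatrix(stdC)[plan@testIdx, ]))
  expect_equal(v1, v2, tolerance = 1e-12)
})

test_that("strong linear signal yields high test AUC through the full kpca pipeline", {
  d <- generateDataset(syntheticSpec(nPerClass = 15, d = 40,
                                     structure = "linear-shift", effect = 4,
                                     noiseSd = 0.5, seed = 91))
  rep5 <- runProtocol(d, "kpca", repeats = 5, seed = 11,
                      kMax = 6, tuneFolds = 5,
                      gammaGrid = 10^seq(-2, 2, length.out = 5))
  expect_gte(rep5@meanAUC, 0.95)
})

test_that("label-permuted data give chance-level AUC", {
  d <- generateDataset(syntheticSpec(nPerClass = 12, d = 30,
                                     structure = "linear-shift", effect = 0,
                                     noiseSd = 1, seed = 92))
  rep10 <- runProtocol(d, "whole", repeats = 10, seed = 13, tuneFolds = 4,
                       gammaGrid = 10^seq(-2, 2, length.out = 5))
  expect_gte(rep10@meanAUC, 0.35)
  expect_lte(rep10@meanAUC, 0.65)
})

test_that("reports serialize and compare via the signed-rank test", {
  d <- generateDataset(syntheticSpec(nPerClass = 10, d = 20,
                                     structure = "linear-shift", effect = 2,
                                     noiseSd = 1, seed = 93))
  rA <- runProtocol(d, "whole", repeats = 6, seed = 19, tuneFolds = 3,
                    gammaGrid = c(0.1, 1, 10))
  rB <- runProtocol(d, "pca", repeats = 6, seed = 19, tuneFolds = 3,
                    kMax = 4, gammaGrid = c(0.1, 1, 10))
  cmp <- compareReports(rA, rB)
  expect_true(cmp$p.value >= 0 && cmp$p.value <= 1)
  base <- withr::local_tempfile()
  writeReport(rA, base)
  js <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  expect_equal(js$mean_auc, rA@meanAUC)
  tab <- read.delim(paste0(base, ".tsv"))
  expect_equal(nrow(tab), 6)
})
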