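test_that("loadDataset parses delimited text and maps labels to {-1,+1}", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("g1,g2,g3,class",
               "1.0,2.0,3.0,A",
               "4.0,5.0,6.0,B",
               "7.0,8.0,9.0,A",
               "1.5,2.5,3.5,B"), path)
  d <- loadDataset(path)
  expect_s4_class(d, "ExpressionDataset")
  expect_equal(dim(d), c(4L, 3L))
  expect_equal(classLabels(d), c(-1, 1, -1, 1))  # A (smaller) -> -1
  expect_equal(featureIds(d), c("g1", "g2", "g3"))
  expect_false(isStandardized(d))
  expect_equal(unname(exprMatrix(d)[2, 3]), 6.0)
})

test_that("loadDataset rejects missing cells (naming them) and one-class labels", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("g1,g2,class", "1,,A", "3,4,B"), path)
  expect_error(loadDataset(path), "row 1, column 'g2'")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("g1,g2,class", "1,2,A", "3,4,A"), path2)
  expect_error(loadDataset(path2), "single class")
})

test_that("dataset writing round-trips through loadDataset", {
  d <- generateDataset(syntheticSpec(nPerClass = 5, d = 8, seed = 11))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeDataset(d, path)
  d2 <- loadDataset(path)
  expect_equal(exprMatrix(d2), exprMatrix(d), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(classLabels(d2), classLabels(d))
})

test_that("standardization uses the population SD on the reference set", {
  d <- expressionDataset(cbind(a = c(1, 2, 3)), c(-1, 1, -1))
  s <- standardizeDataset(d)
  expect_equal(as.numeric(exprMatrix(s)), c(-1.2247, 0, 1.2247),
               tolerance = 1e-4)

  # reference {1,2} of column (1,3,5): mean 2, population sd 1 -> (-1, +1, 3)
  d2 <- expressionDataset(cbind(a = c(1, 3, 5)), c(-1, 1, -1))
  s2 <- standardizeDataset(d2, referenceIndices = c(1, 2))
  expect_equal(as.numeric(exprMatrix(s2)), c(-1, 1, 3), tolerance = 1e-12)
})

test_that("constant reference features are centered but not scaled", {
  d <- expressionDataset(cbind(a = c(5, 5, 7)), c(-1, 1, -1))
  expect_warning(s <- standardizeDataset(d, referenceIndices = c(1, 2)),
                 "constant")
  expect_equal(as.numeric(exprMatrix(s)), c(0, 0, 2))
})

test_that("standardize then inverse-transform recovers the data", {
  d <- generateDataset(syntheticSpec(nPerClass = 8, d = 20, seed = 4))
  plan <- stratifiedSplit(d, 2 / 3, seed = 1)
  s <- standardizeDataset(d, plan@trainIdx)
  expect_true(isStandardized(s))
  # training features have population mean 0 and variance 1
  ref <- exprMatrix(s)[plan@trainIdx, ]
  expect_lt(max(abs(colMeans(ref))), 1e-8)
  n <- nrow(ref)
  popVar <- colSums(sweep(ref, 2, colMeans(ref))^2) / n
  expect_lt(max(abs(popVar - 1)), 1e-8)
  back <- inverseStandardize(s)
  expect_lt(max(abs(exprMatrix(back) - exprMatrix(d))), 1e-10)
})

test_that("stratified split honours per-class counts and determinism", {
  # class sizes (8, 24) at fraction 2/3 -> train (5, 16)
  y <- rep(c("A", "B"), times = c(8, 24))
  d <- expressionDataset(matrix(rnorm(32 * 3), 32, 3), y)
  plan <- stratifiedSplit(d, 2 / 3, seed = 5)
  trainY <- classLabels(d)[plan@trainIdx]
  expect_equal(sum(trainY == -1), 5)
  expect_equal(sum(trainY == 1), 16)
  expect_setequal(c(plan@trainIdx, plan@testIdx), 1:32)

  plan2 <- stratifiedSplit(d, 2 / 3, seed = 5)
  expect_identical(plan@trainIdx, plan2@trainIdx)
  expect_error(stratifiedSplit(d, 1.0), "between 0 and 1")

  one <- expressionDataset(matrix(rnorm(9), 3, 3), c("A", "A", "B"))
  expect_error(stratifiedSplit(one, 0.5), "at least 2 samples")
})

test_that("per-class train fractions track the target over many class sizes", {
  set.seed(202)
  fracs <- c()
  for (i in 1:60) {
    n1 <- sample(5:40, 1)
    n2 <- sample(5:40, 1)
    d <- expressionDataset(matrix(rnorm((n1 + n2) * 2), n1 + n2, 2),
                           rep(c("A", "B"), times = c(n1, n2)))
    plan <- stratifiedSplit(d, 2 / 3, seed = i)
    trainY <- classLabels(d)[plan@trainIdx]
    fracs <- c(fracs, sum(trainY == -1) / n1, sum(trainY == 1) / n2)
  }
  expect_lt(abs(mean(fracs) - 2 / 3), 0.02)
})
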