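test_that("degenerate data give a zero leave-one-out score integral", {
  X <- matrix(1, 5, 3) + 0  # all samples identical
  expect_equal(suppressWarnings(looScoreIntegral(X, rbfKernel(1), 1, 2)), 0)
})

test_that("looScoreIntegral matches the longhand loop oracle", {
  set.seed(41)
  X <- matrix(rnorm(15), 5, 3)
  h <- 1.3
  Jorc <- longhandSurface(X, h, kMax = 3)
  # oracle column n is (1/N) * cumulative sum; invert to per-(n) sums
  perComp <- diff(c(0, Jorc[1, ])) * nrow(X)
  for (n in 1:3) {
    total <- sum(vapply(1:5, function(j)
      looScoreIntegral(X, rbfKernel(h), n, j), numeric(1)))
    expect_equal(total, perComp[n], tolerance = 1e-10)
  }
})

test_that("component index beyond the held-out rank contributes zero", {
  X <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  # leave-one-out model has 3 samples -> rank <= 2
  expect_warning(v <- looScoreIntegral(X, rbfKernel(1), 3, 1), "rank")
  expect_equal(v, 0)
})

test_that("linear-kernel integrals scale as c^2 when X is scaled by c", {
  set.seed(42)
  X <- matrix(rnorm(18), 6, 3)
  c0 <- 3.7
  i1 <- looScoreIntegral(X, linearKernel(), 1, 2)
  i2 <- looScoreIntegral(c0 * X, linearKernel(), 1, 2)
  expect_equal(i2 / i1, c0^2, tolerance = 1e-8)
})

test_that("criterion J is zero at k = 0 and non-decreasing in k", {
  d <- randomDataset(8, 3, seed = 43)
  spec <- rbfKernel(1.5)
  expect_equal(criterionJ(d, spec, 0), 0)
  Js <- vapply(1:5, function(k) criterionJ(d, spec, k), numeric(1))
  expect_true(all(diff(Js) >= -1e-12))
  expect_error(criterionJ(d, spec, 7), "k must satisfy")
})

test_that("leave-one-out equals v-fold with v = N exactly", {
  d <- randomDataset(7, 3, seed = 44)
  spec <- rbfKernel(2)
  expect_identical(criterionJ(d, spec, 3, cv = "loo"),
                   criterionJ(d, spec, 3, cv = "vfold", v = 7))
})

test_that("v-fold criterion is deterministic given the fold seed", {
  d <- randomDataset(9, 3, seed = 45)
  spec <- rbfKernel(1.2)
  a <- criterionJ(d, spec, 3, cv = "vfold", v = 3, seed = 10)
  b <- criterionJ(d, spec, 3, cv = "vfold", v = 3, seed = 10)
  c3 <- criterionJ(d, spec, 3, cv = "vfold", v = 3, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, c3))
})

test_that("selection surface matches the longhand oracle on small data", {
  for (seed in 1:3) {
    X <- exprMatrix(randomDataset(7, 3, seed = 50 + seed))
    hGrid <- c(0.8, 1.6, 3.2)
    surf <- selectBandwidthAndK(X, hGrid = hGrid, kMax = 4, rescale = FALSE)
    Jorc <- longhandSurface(X, hGrid, 4)
    expect_equal(criterionValues(surf), Jorc, ignore_attr = TRUE,
                 tolerance = 1e-9)
  }
})

test_that("rescaling the surface to max 1 never moves the argmax", {
  X <- exprMatrix(randomDataset(8, 4, seed = 54))
  hGrid <- c(0.5, 1, 2, 4)
  raw <- selectBandwidthAndK(X, hGrid = hGrid, kMax = 4, rescale = FALSE)
  scl <- selectBandwidthAndK(X, hGrid = hGrid, kMax = 4, rescale = TRUE)
  expect_equal(max(criterionValues(scl)), 1)
  expect_identical(selectedBandwidth(raw), selectedBandwidth(scl))
  expect_identical(selectedComponents(raw), selectedComponents(scl))
  expect_equal(criterionValues(scl) * max(criterionValues(raw)),
               criterionValues(raw), tolerance = 1e-12)
})

test_that("rank-1 data with tiny noise select a single linear component", {
  set.seed(55)
  n <- 12
  factor <- rnorm(n)
  load <- rnorm(6)
  X <- factor %o% load + matrix(rnorm(n * 6, sd = 0.01 * sd(factor)), n, 6)
  surf <- selectPCAComponents(X, kMax = 6)
  expect_equal(selectedComponents(surf), 1L)
  expect_true(all(diff(criterionValues(surf)[1, ]) >= -1e-12))
})

test_that("surface export writes the long table and JSON summary", {
  X <- exprMatrix(randomDataset(7, 3, seed = 56))
  surf <- selectBandwidthAndK(X, hGrid = c(1, 2), kMax = 3)
  base <- withr::local_tempfile()
  writeSurface(surf, base)
  long <- read.delim(paste0(base, ".tsv"))
  expect_equal(nrow(long), 2 * 3)
  expect_equal(long$J, as.vector(criterionValues(surf)), tolerance = 1e-12)
  js <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  expect_equal(js$h_hat, selectedBandwidth(surf))
  expect_equal(js$k_hat, selectedComponents(surf))
})

test_that("default bandwidth grid spans 0.1x to 10x the median distance", {
  X <- exprMatrix(randomDataset(10, 4, seed = 57))
  g <- defaultBandwidthGrid(X)
  med <- median(dist(X))
  expect_length(g, 30)
  expect_equal(g[1], 0.1 * med, tolerance = 1e-12)
  expect_equal(g[30], 10 * med, tolerance = 1e-12)
  expect_true(all(diff(log(g)) > 0))
})
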