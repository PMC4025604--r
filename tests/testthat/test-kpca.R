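test_that("two distinct points give exactly one non-degenerate component", {
  X <- rbind(c(0, 0), c(1, 2))
  m <- fitKPCA(X, rbfKernel(1), k = 1)
  expect_gt(eigenvalues(m)[1], 1e-12)
  ev <- eigen(centerGram(gramMatrix(X, rbfKernel(1))),
              symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(ev > 1e-12), 1)
})

test_that("linear-kernel eigenvalues equal squared singular values of centered X", {
  d <- randomDataset(12, 5, seed = 21)
  k <- 5
  m <- fitLinearPCA(d, k)
  Xc <- scale(exprMatrix(d), center = TRUE, scale = FALSE)
  expect_equal(eigenvalues(m), svd(Xc)$d[1:k]^2, tolerance = 1e-8)
})

test_that("large-bandwidth RBF leading eigenvector converges to linear PCA's", {
  d <- randomDataset(15, 4, seed = 22)
  scale <- max(abs(exprMatrix(d)))
  mR <- fitKPCA(d, rbfKernel(1e6 * scale), k = 1)
  mL <- fitLinearPCA(d, 1)
  cosine <- abs(sum(dualCoef(mR)[, 1] * dualCoef(mL)[, 1]))
  expect_gte(cosine, 0.999)
})

test_that("training scores reproduce lambda_n alpha^(n) and sum to zero", {
  d <- randomDataset(10, 6, seed = 23)
  m <- fitKPCA(d, rbfKernel(2), k = 4)
  Z <- scores(m)
  expect_equal(Z, dualCoef(m) %*% diag(eigenvalues(m)),
               ignore_attr = TRUE, tolerance = 1e-8)
  expect_lt(max(abs(colSums(Z))), 1e-6)
})

test_that("a duplicated training point scores identically out of sample", {
  d <- randomDataset(9, 4, seed = 24)
  m <- fitKPCA(d, rbfKernel(1.5), k = 3)
  Ztr <- scores(m)
  Zts <- scores(m, exprMatrix(d)[4, , drop = FALSE])
  expect_equal(as.numeric(Zts), as.numeric(Ztr[4, ]), tolerance = 1e-8)
})

test_that("linear-kernel scores match the covariance-eigendecomposition oracle", {
  d <- randomDataset(11, 4, seed = 25)
  X <- exprMatrix(d)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  m <- fitLinearPCA(d, 3)
  Z <- scores(m)
  # projections onto unit principal axes, scaled: z_n = sqrt(lambda_n) u_n
  sv <- svd(Xc)
  for (n in 1:3) {
    proj <- Xc %*% sv$v[, n] * sv$d[n]
    ratio <- Z[, n] / proj
    expect_lt(max(abs(abs(ratio) - abs(ratio[1]))), 1e-6)  # fixed scale
    expect_lt(diff(range(ratio)), 1e-6)                    # consistent sign
  }
})

test_that("points on a line give one component with collinear scores", {
  t <- c(-2, -1, 0.5, 1, 3)
  X <- cbind(t, 2 * t)
  expect_warning(m <- fitLinearPCA(X, k = 2), "degenerate")
  expect_gt(eigenvalues(m)[1], 1e-10)
  expect_lt(eigenvalues(m)[2], 1e-10)
  Z <- scores(m)
  pos <- t - mean(t)  # signed position along the line
  ratio <- Z[, 1] / pos
  expect_lt(diff(range(ratio)), 1e-8)
})

test_that("linear PCA eigenvalues are rotation invariant", {
  d <- randomDataset(10, 4, seed = 26)
  X <- exprMatrix(d)
  set.seed(27)
  Q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  expect_equal(eigenvalues(fitLinearPCA(X, 4)),
               eigenvalues(fitLinearPCA(X %*% Q, 4)), tolerance = 1e-8)
})

test_that("eigenvector columns are orthonormal and spectrum matches trace", {
  d <- randomDataset(9, 5, seed = 28)
  N <- 9
  m <- fitKPCA(d, rbfKernel(1.8), k = N - 1)
  A <- dualCoef(m)
  expect_equal(crossprod(A), diag(N - 1), ignore_attr = TRUE,
               tolerance = 1e-8)
  # centered Gram has rank <= N-1; the discarded eigenvalue is 0
  Kc <- centerGram(gramMatrix(exprMatrix(d), rbfKernel(1.8)))
  expect_equal(sum(eigenvalues(m)), sum(diag(Kc)),
               tolerance = 1e-6 * sum(diag(Kc)))
})

test_that("explained-variance ratio is non-decreasing and reaches 1", {
  d <- randomDataset(8, 3, seed = 29)
  m <- fitKPCA(d, rbfKernel(1.2), k = 7)
  lam <- eigenvalues(m)
  ratio <- cumsum(lam) / sum(lam)
  expect_true(all(diff(ratio) >= -1e-12))
  expect_equal(ratio[length(ratio)], 1, tolerance = 1e-10)
})

test_that("k out of range is rejected", {
  d <- randomDataset(6, 3, seed = 30)
  expect_error(fitKPCA(d, rbfKernel(1), k = 6), "k must satisfy")
  expect_error(fitKPCA(d, rbfKernel(1), k = 0), "k must satisfy")
})

test_that("RBF eigenvalues agree with an independent KPCA implementation", {
  skip_if_not_installed("kernlab")
  d <- randomDataset(14, 5, seed = 31)
  h <- 1.7
  m <- fitKPCA(d, rbfKernel(h), k = 6)
  km <- kernlab::kpca(exprMatrix(d),
                      kernel = "rbfdot",
                      kpar = list(sigma = 1 / (2 * h^2)), features = 6)
  # kernlab reports eigenvalues of the centered Gram matrix divided by N
  expect_equal(eigenvalues(m), kernlab::eig(km) * nrow(exprMatrix(d)),
               ignore_attr = TRUE, tolerance = 1e-6)
})

test_that("KPCA models round-trip through the JSON container", {
  d <- randomDataset(8, 4, seed = 32)
  m <- fitKPCA(d, rbfKernel(2.2), k = 3)
  path <- withr::local_tempfile(fileext = ".json")
  writeKPCAModel(m, path)
  m2 <- readKPCAModel(path)
  expect_equal(dualCoef(m2), dualCoef(m), tolerance = 1e-12)
  expect_equal(eigenvalues(m2), eigenvalues(m), tolerance = 1e-12)
  Znew <- matrix(rnorm(8), 2, 4)
  expect_equal(scores(m2, Znew), scores(m, Znew), tolerance = 1e-10)
})
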