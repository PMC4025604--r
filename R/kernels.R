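# Kernel evaluations, Gram matrices, and the double-centering operator that
# yields the centered kernel matrix Omega_c.

#' Evaluate a kernel on a pair of feature vectors
#'
#' RBF: \eqn{\exp(-\|a-b\|^2/(2h^2))} (note the factor 2 in the denominator);
#' linear: \eqn{a^T b}; polynomial: \eqn{(a^T b + c)^p}.
#'
#' @param a,b numeric vectors of equal length.
#' @param spec a [KernelSpec-class].
#' @return A single numeric kernel value.
#' @examples
#' kernelValue(c(1, 2), c(3, 4), linearKernel())  # 11
#' @export
kernelValue <- function(a, b, spec) {
  stopifnot(is(spec, "KernelSpec"))
  if (length(a) != length(b))
    stop("vectors must have the same dimension (", length(a),
         " vs ", length(b), ")")
  switch(spec@family,
    rbf = exp(-sum((a - b)^2) / (2 * spec@h^2)),
    linear = sum(a * b),
    polynomial = (sum(a * b) + spec@offset)^spec@degree)
}

#' Gram matrix of a sample set
#'
#' Entry (i, j) is the kernel value of rows i and j of `X`. For the RBF
#' kernel the diagonal is identically 1.
#'
#' @param X numeric matrix, samples in rows (N >= 2).
#' @param spec a [KernelSpec-class].
#' @return A symmetric N x N matrix.
#' @export
gramMatrix <- function(X, spec) {
  stopifnot(is(spec, "KernelSpec"))
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 samples")
  G <- tcrossprod(X)
  K <- switch(spec@family,
    linear = G,
    polynomial = (G + spec@offset)^spec@degree,
    rbf = {
      sq <- diag(G)
      D2 <- outer(sq, sq, "+") - 2 * G
      D2[D2 < 0] <- 0  # guard rounding on near-duplicates
      exp(-D2 / (2 * spec@h^2))
    })
  (K + t(K)) / 2
}

#' Double-center a kernel matrix
#'
#' Applies the four-term centering
#' \deqn{\Omega_{c,ij} = K_{ij} - \frac1N\sum_r K_{ir} - \frac1N\sum_r K_{jr}
#'   + \frac1{N^2}\sum_{r,s} K_{rs},}
#' equivalent to centering the implicit feature map at its empirical mean.
#' The result is symmetric, has zero row sums, and is positive semi-definite
#' whenever K is.
#'
#' @param K symmetric kernel matrix (asymmetry beyond 1e-8 is an error).
#' @return The centered N x N matrix.
#' @export
centerGram <- function(K) {
  K <- as.matrix(K)
  if (nrow(K) != ncol(K)) stop("K must be square")
  asym <- max(abs(K - t(K)))
  if (asym > 1e-8)
    stop("K is not symmetric (max |K - t(K)| = ", format(asym), ")")
  rm <- rowMeans(K)
  gm <- mean(K)
  Kc <- K - outer(rm, rep(1, ncol(K))) - outer(rep(1, nrow(K)), rm) + gm
  (Kc + t(Kc)) / 2
}

#' Centered cross-kernel between test points and a training set
#'
#' Out-of-sample analogue of [centerGram()]: entry (t, i) is
#' \deqn{K(x^*_t, x_i) - \frac1N\sum_r K(x^*_t, x_r)
#'   - \frac1N\sum_r K(x_i, x_r) + \frac1{N^2}\sum_{r,s} K(x_r, x_s),}
#' i.e. the inner product of the centered feature maps of \eqn{x^*_t} and
#' \eqn{x_i}, where centering always uses the training empirical mean. With
#' `testX = trainX` this reproduces `centerGram(gramMatrix(trainX, spec))`.
#'
#' @param trainX N x d training matrix.
#' @param testX M x d matrix of evaluation points.
#' @param spec a [KernelSpec-class].
#' @param trainRowMeans,trainGrandMean optional precomputed centering
#'   statistics of the uncentered training kernel matrix (recomputed when
#'   missing).
#' @return An M x N matrix.
#' @export
crossCenteredKernel <- function(trainX, testX, spec,
                                trainRowMeans = NULL, trainGrandMean = NULL) {
  trainX <- as.matrix(trainX)
  if (!is.matrix(testX)) testX <- matrix(testX, nrow = 1L)
  if (ncol(testX) != ncol(trainX))
    stop("test points have ", ncol(testX), " features; training set has ",
         ncol(trainX))
  if (is.null(trainRowMeans) || is.null(trainGrandMean)) {
    Ktr <- gramMatrix(trainX, spec)
    trainRowMeans <- rowMeans(Ktr)
    trainGrandMean <- mean(Ktr)
  }
  Kx <- crossKernel(testX, trainX, spec)
  Kx - rowMeans(Kx) -
    matrix(trainRowMeans, nrow(Kx), ncol(Kx), byrow = TRUE) + trainGrandMean
}

# Uncentered M x N kernel matrix between two sample sets.
crossKernel <- function(A, B, spec) {
  G <- tcrossprod(A, B)
  switch(spec@family,
    linear = G,
    polynomial = (G + spec@offset)^spec@degree,
    rbf = {
      D2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * G
      D2[D2 < 0] <- 0
      exp(-D2 / (2 * spec@h^2))
    })
}
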