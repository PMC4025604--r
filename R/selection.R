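# Leave-one-out selection criterion for the RBF bandwidth and the number of
# retained kernel principal components, and its linear-PCA specialization.
#
# The criterion for bandwidth h and component count k is
#   J(h, k) = (1/N) sum_{n=1..k} sum_{j=1..N} integral |z_n^(-j)(x)| dx
# where z_n^(-j) is the score function on component n of a kernel PCA model
# fitted with sample j left out. The integral has no defined domain for
# d-dimensional x; here it is approximated by evaluating |z_n^(-j)| at all N
# samples (canonical dataset order) and applying the unit-spaced trapezoidal
# rule to that vector. The bandwidth maximizing J is selected; since J is
# non-decreasing in k (a sum of non-negative per-component integrals), k is
# selected by an elbow rule on the marginal gains.

# Trapezoidal rule with unit spacing over a vector of values.
trapezoid <- function(v) {
  n <- length(v)
  if (n < 2L) return(0)
  sum(v) - (v[1L] + v[n]) / 2
}

#' Leave-one-out score integral for one component and one held-out sample
#'
#' Fits a KPCA model on the N - 1 samples excluding `j`, evaluates the n-th
#' score function at all N samples (the held-out sample is scored
#' out-of-sample through the centered cross-kernel), and returns the
#' trapezoidal integral of the absolute scores. When `n` exceeds the
#' numerical rank of the reduced problem the contribution is 0, with a
#' warning.
#'
#' @param data an [ExpressionDataset-class] or numeric matrix (N >= 3).
#' @param spec a [KernelSpec-class].
#' @param n component index.
#' @param j index of the held-out sample.
#' @return A non-negative scalar.
#' @export
looScoreIntegral <- function(data, spec, n, j) {
  X <- if (is(data, "ExpressionDataset")) exprMatrix(data) else as.matrix(data)
  if (nrow(X) < 3L) stop("need N >= 3 samples")
  ints <- heldOutIntegrals(X, spec, kMax = n, holdOut = j)
  if (ints$rank < n) {
    warning("component ", n, " exceeds the rank (", ints$rank,
            ") of the leave-one-out problem; contribution 0")
    return(0)
  }
  ints$integrals[n]
}

# Fit on X[-holdOut, ], score all N rows of X, and return the trapezoidal
# integrals of |z_n| for n = 1..kMax, plus the numerical rank of the reduced
# centered Gram matrix. Components beyond the rank get integral 0.
heldOutIntegrals <- function(X, spec, kMax, holdOut) {
  keep <- setdiff(seq_len(nrow(X)), holdOut)
  Xr <- X[keep, , drop = FALSE]
  K <- gramMatrix(Xr, spec)
  Kc <- centerGram(K)
  eg <- eigen(Kc, symmetric = TRUE)
  lam <- eg$values
  rank <- sum(lam > .EIG_FLOOR)
  kUse <- min(kMax, rank)
  integrals <- numeric(kMax)
  if (kUse >= 1L) {
    A <- eg$vectors[, seq_len(kUse), drop = FALSE]
    Z <- crossCenteredKernel(Xr, X, spec,
                             trainRowMeans = rowMeans(K),
                             trainGrandMean = mean(K)) %*% A
    integrals[seq_len(kUse)] <- apply(abs(Z), 2L, trapezoid)
  }
  list(integrals = integrals, rank = rank)
}

# Cross-validated criterion profile J(k) for k = 1..kMax at a fixed kernel.
# folds: list of held-out index groups (LOO: singletons). Each group's model
# is shared across its members, so a group of size g contributes g times its
# integrals. Returns the cumulative profile (1/N) * cumsum over components.
criterionProfile <- function(X, spec, kMax, folds) {
  N <- nrow(X)
  perComp <- numeric(kMax)
  droppedRank <- FALSE
  for (grp in folds) {
    ints <- heldOutIntegrals(X, spec, kMax, holdOut = grp)
    if (ints$rank < kMax) droppedRank <- TRUE
    perComp <- perComp + length(grp) * ints$integrals
  }
  if (droppedRank)
    warning("some components exceeded the rank of a held-out fit; ",
            "their contributions are 0")
  cumsum(perComp) / N
}

#' Cross-validated selection criterion J for a fixed kernel and k
#'
#' \eqn{J(h,k) = \frac1N \sum_{n=1}^{k} \sum_{j=1}^{N} \int
#' |z_n^{(-j)}(x)|\,dx}, evaluated by the trapezoidal rule over the absolute
#' scores at all N samples (see [looScoreIntegral()]). `cv = "loo"` refits
#' with each single sample held out; `cv = "vfold"` partitions the samples
#' into `v` seeded groups and shares each group's model across its members
#' (with v = N this reproduces LOO exactly). The seed is used only for fold
#' assignment.
#'
#' @param data an [ExpressionDataset-class] or numeric matrix.
#' @param spec a [KernelSpec-class].
#' @param k number of components summed, `1 <= k <= N - 2` (a model on N - 1
#'   samples has rank at most N - 2); `k = 0` returns 0.
#' @param cv `"loo"` or `"vfold"`.
#' @param v number of folds for `cv = "vfold"`.
#' @param seed integer seed for fold assignment.
#' @return A non-negative scalar.
#' @export
criterionJ <- function(data, spec, k, cv = c("loo", "vfold"), v = 10L,
                       seed = 1L) {
  X <- if (is(data, "ExpressionDataset")) exprMatrix(data) else as.matrix(data)
  cv <- match.arg(cv)
  N <- nrow(X)
  k <- as.integer(k)
  if (k == 0L) return(0)
  if (k < 0L || k > N - 2L)
    stop("k must satisfy 0 <= k <= N - 2 (k = ", k, ", N = ", N, ")")
  folds <- makeFolds(N, cv, v, seed)
  profile <- criterionProfile(X, spec, k, folds)
  profile[k]
}

# Seeded fold assignment (unsupervised; no stratification). LOO gives
# singleton groups in canonical order.
makeFolds <- function(N, cv, v, seed) {
  if (cv == "loo" || (cv == "vfold" && v >= N))
    return(as.list(seq_len(N)))
  if (v < 2L) stop("v must be >= 2")
  perm <- localRNG(seed)$permute(seq_len(N))
  split(perm, rep_len(seq_len(v), N))
}

#' Default bandwidth grid
#'
#' 30 logarithmically spaced values from 0.1x to 10x the median pairwise
#' Euclidean distance of the samples — the scale range within which RBF
#' geometry transitions from near-diagonal to near-constant kernels.
#'
#' @param X numeric samples x features matrix (or [ExpressionDataset-class]).
#' @param length number of grid points.
#' @param lower,upper multipliers of the median pairwise distance.
#' @return A numeric vector of bandwidths.
#' @export
defaultBandwidthGrid <- function(X, length = 30L, lower = 0.1, upper = 10) {
  if (is(X, "ExpressionDataset")) X <- exprMatrix(X)
  med <- stats::median(stats::dist(X))
  if (!is.finite(med) || med <= 0)
    stop("median pairwise distance is not positive; cannot build a grid")
  exp(seq(log(lower * med), log(upper * med), length.out = length))
}

#' Select the RBF bandwidth and number of components
#'
#' Evaluates the criterion surface J(h, k) on a bandwidth grid and k = 1..
#' `kMax`, selects the bandwidth whose profile attains the surface maximum
#' (J is non-decreasing in k, so the maximum over the surface is the maximum
#' of the k = kMax column), and selects k by the elbow rule: the smallest k
#' whose next marginal gain J(h, k+1) - J(h, k) falls below `epsilon` times
#' the largest marginal gain at the selected bandwidth. The surface is
#' rescaled to maximum 1 when `rescale = TRUE` (the argmax is invariant).
#'
#' @param data an [ExpressionDataset-class] or numeric matrix.
#' @param hGrid bandwidth grid; defaults to [defaultBandwidthGrid()].
#' @param kMax largest component count, `<= N - 2`; defaults to
#'   `min(N - 2, 15)`.
#' @param cv,v,seed cross-validation mode, fold count and fold seed, as in
#'   [criterionJ()]. Default CV switches from leave-one-out to 10-fold when
#'   N > 150 (cost of N refits per bandwidth).
#' @param epsilon elbow threshold, fraction of the largest marginal gain.
#' @param rescale divide J by its maximum.
#' @return A [SelectionSurface-class].
#' @export
selectBandwidthAndK <- function(data, hGrid = NULL, kMax = NULL,
                                cv = NULL, v = 10L, seed = 1L,
                                epsilon = 0.01, rescale = TRUE) {
  X <- if (is(data, "ExpressionDataset")) exprMatrix(data) else as.matrix(data)
  N <- nrow(X)
  if (is.null(hGrid)) hGrid <- defaultBandwidthGrid(X)
  if (any(!is.finite(hGrid)) || any(hGrid <= 0))
    stop("hGrid must contain positive finite bandwidths")
  if (is.null(kMax)) kMax <- min(N - 2L, 15L)
  kMax <- as.integer(kMax)
  if (kMax < 1L || kMax > N - 2L)
    stop("kMax must satisfy 1 <= kMax <= N - 2")
  if (is.null(cv)) cv <- if (N > 150L) "vfold" else "loo"
  cv <- match.arg(cv, c("loo", "vfold"))
  folds <- makeFolds(N, cv, v, seed)
  J <- matrix(0, length(hGrid), kMax)
  for (i in seq_along(hGrid)) {
    prof <- criterionProfile(X, rbfKernel(hGrid[i]), kMax, folds)
    if (any(!is.finite(prof))) {
      warning("non-finite criterion values at h = ", signif(hGrid[i], 4),
              "; set to 0")
      prof[!is.finite(prof)] <- 0
    }
    J[i, ] <- prof
  }
  finalizeSurface(J, hGrid, kMax, cv, v, epsilon, rescale)
}

# Shared selection logic: bandwidth by surface argmax, k by elbow rule,
# optional rescaling to maximum 1.
finalizeSurface <- function(J, hGrid, kMax, cv, v, epsilon, rescale) {
  iHat <- which.max(J[, kMax])
  prof <- J[iHat, ]
  gains <- diff(c(0, prof))
  kHat <- elbowK(gains, epsilon)
  if (rescale && max(J) > 0) J <- J / max(J)
  new("SelectionSurface", hGrid = hGrid, kGrid = seq_len(kMax), J = J,
      hHat = hGrid[iHat], kHat = kHat, cvMode = cv,
      v = as.integer(if (cv == "vfold") v else 0L),
      rescaled = isTRUE(rescale))
}

# Smallest k whose next marginal gain drops below epsilon * max gain
# (kMax when no gain ever drops below).
elbowK <- function(gains, epsilon) {
  thr <- epsilon * max(gains, 0)
  kMax <- length(gains)
  for (k in seq_len(kMax - 1L)) if (gains[k + 1L] < thr) return(k)
  kMax
}

#' Select the number of components for linear PCA
#'
#' The linear-kernel specialization of the selection criterion: a single
#' criterion profile over k with no bandwidth dimension,
#' \eqn{J(k) = \frac1N \sum_{n \le k} \sum_j \int |z_n^{pca(-j)}(x)|\,dx},
#' with the same leave-one-out machinery, trapezoidal integration and elbow
#' rule.
#'
#' @inheritParams selectBandwidthAndK
#' @return A [SelectionSurface-class] with a single (NA) bandwidth row.
#' @export
selectPCAComponents <- function(data, kMax = NULL, cv = NULL, v = 10L,
                                seed = 1L, epsilon = 0.01, rescale = TRUE) {
  X <- if (is(data, "ExpressionDataset")) exprMatrix(data) else as.matrix(data)
  N <- nrow(X)
  if (is.null(kMax)) kMax <- min(N - 2L, 15L)
  kMax <- as.integer(kMax)
  if (kMax < 1L || kMax > N - 2L)
    stop("kMax must satisfy 1 <= kMax <= N - 2")
  if (is.null(cv)) cv <- if (N > 150L) "vfold" else "loo"
  cv <- match.arg(cv, c("loo", "vfold"))
  folds <- makeFolds(N, cv, v, seed)
  prof <- criterionProfile(X, linearKernel(), kMax, folds)
  J <- matrix(prof, nrow = 1L)
  gains <- diff(c(0, prof))
  kHat <- elbowK(gains, epsilon)
  if (rescale && max(J) > 0) J <- J / max(J)
  new("SelectionSurface", hGrid = NA_real_, kGrid = seq_len(kMax), J = J,
      hHat = NA_real_, kHat = kHat, cvMode = cv,
      v = as.integer(if (cv == "vfold") v else 0L),
      rescaled = isTRUE(rescale))
}

#' Export a selection surface
#'
#' Writes the criterion surface as long-format delimited text (columns h, k,
#' J) plus a JSON summary holding the selected parameters, CV mode and
#' grids.
#'
#' @param surface a [SelectionSurface-class].
#' @param path base path; `<path>.tsv` and `<path>.json` are written.
#' @return Invisibly, the two paths written.
#' @export
writeSurface <- function(surface, path) {
  stopifnot(is(surface, "SelectionSurface"))
  long <- expand.grid(h = surface@hGrid, k = surface@kGrid)
  long$J <- as.vector(surface@J)
  tsv <- paste0(path, ".tsv")
  json <- paste0(path, ".json")
  utils::write.table(long, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(h_hat = surface@hHat, k_hat = surface@kHat,
         cv_mode = surface@cvMode,
         v = if (surface@cvMode == "vfold") surface@v else NULL,
         rescaled = surface@rescaled,
         h_grid = surface@hGrid, k_grid = surface@kGrid),
    json, digits = NA, auto_unbox = TRUE, na = "null", null = "null")
  invisible(c(tsv, json))
}

#' Plot a selection surface
#'
#' Heat map of J over the (h, k) grid (log-scaled bandwidth axis) with the
#' selected point marked; for single-bandwidth (PCA) surfaces, the J(k)
#' profile.
#'
#' @param x a [SelectionSurface-class].
#' @param y unused.
#' @param ... passed to the underlying plot.
#' @export
setMethod("plot", signature(x = "SelectionSurface", y = "missing"),
  function(x, y, ...) {
    if (length(x@hGrid) == 1L || all(is.na(x@hGrid))) {
      graphics::plot(x@kGrid, x@J[1L, ], type = "b", xlab = "components k",
                     ylab = "J(k)", ...)
      graphics::abline(v = x@kHat, lty = 2)
    } else {
      graphics::image(log10(x@hGrid), x@kGrid, x@J,
                      xlab = "log10 bandwidth h", ylab = "components k",
                      main = "selection criterion J(h, k)", ...)
      graphics::points(log10(x@hHat), x@kHat, pch = 4, cex = 2, lwd = 2)
    }
    invisible(x)
  })
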