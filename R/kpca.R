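# Kernel PCA via the eigendecomposition of the centered Gram matrix
# (the least-squares SVM formulation: the dual problem is
# Omega_c alpha = lambda alpha), with out-of-sample scoring and linear PCA
# as the linear-kernel special case.

# Eigenvalues below this absolute floor are treated as numerically zero
# (rank decisions, warnings).
.EIG_FLOOR <- 1e-12

#' Fit kernel PCA
#'
#' Computes the top-k eigenpairs of the double-centered Gram matrix
#' \eqn{\Omega_c} of the training samples, \eqn{\Omega_c\alpha =
#' \lambda\alpha}. Eigenvectors are returned with unit Euclidean norm and the
#' sign convention that each column's largest-magnitude entry is positive
#' (removes eigensolver sign nondeterminism). With this normalization the
#' training-sample score on component n equals \eqn{\lambda_n \alpha^{(n)}}.
#'
#' @param data an [ExpressionDataset-class] or a numeric samples x features
#'   matrix.
#' @param spec a [KernelSpec-class].
#' @param k number of components to retain, `1 <= k <= N - 1` (the centered
#'   Gram matrix has rank at most N - 1).
#' @param centered fit on the centered Gram matrix (default TRUE). FALSE
#'   poses the eigenproblem on the raw Gram matrix, the plain linear-PCA
#'   score formulation; out-of-sample scoring then also uses the uncentered
#'   kernel.
#' @return A [KPCAModel-class].
#' @examples
#' X <- matrix(rnorm(40), 10, 4)
#' fitKPCA(X, rbfKernel(2), k = 3)
#' @export
fitKPCA <- function(data, spec, k, centered = TRUE) {
  X <- if (is(data, "ExpressionDataset")) exprMatrix(data) else as.matrix(data)
  N <- nrow(X)
  k <- as.integer(k)
  if (k < 1L || k > N - 1L)
    stop("k must satisfy 1 <= k <= N - 1 (k = ", k, ", N = ", N, ")")
  K <- gramMatrix(X, spec)
  Kc <- if (centered) centerGram(K) else K
  eg <- eigen(Kc, symmetric = TRUE)
  lam <- eg$values[seq_len(k)]
  A <- eg$vectors[, seq_len(k), drop = FALSE]
  A <- fixSigns(A)
  if (any(lam < .EIG_FLOOR))
    warning(sum(lam < .EIG_FLOOR), " retained eigenvalue(s) below ",
            .EIG_FLOOR, "; component(s) kept but numerically degenerate")
  tol <- 1e-8 * max(abs(lam[1L]), .EIG_FLOOR)
  lam[lam < 0 & lam > -tol] <- 0  # clamp eigensolver noise
  new("KPCAModel", spec = spec, trainX = X, alphas = A,
      eigenvalues = lam, k = k,
      kRowMeans = rowMeans(K), kGrandMean = mean(K),
      centered = isTRUE(centered))
}

#' Fit linear PCA through the Gram-matrix eigenproblem
#'
#' Identical machinery to [fitKPCA()] with the linear kernel: the dual
#' eigenproblem on the centered Gram matrix, whose eigenvalues equal the
#' squared singular values of the column-mean-centered data matrix.
#'
#' @inheritParams fitKPCA
#' @return A [KPCAModel-class] with a linear [KernelSpec-class].
#' @export
fitLinearPCA <- function(data, k, centered = TRUE)
  fitKPCA(data, linearKernel(), k, centered = centered)

# Make the largest-magnitude entry of each column positive.
fixSigns <- function(A) {
  for (j in seq_len(ncol(A))) {
    i <- which.max(abs(A[, j]))
    if (A[i, j] < 0) A[, j] <- -A[, j]
  }
  A
}

#' Score variables (projections onto kernel principal components)
#'
#' The score of point x on component n is \eqn{z_n(x) = \sum_i
#' \alpha_i^{(n)} K_c(x_i, x)} where \eqn{K_c} is the centered kernel (the
#' same centered feature map the model was fitted with; the uncentered kernel
#' is used when the model was fitted with `centered = FALSE`). For the
#' training samples this reproduces \eqn{z_n = \lambda_n \alpha^{(n)}}.
#'
#' @param object a [KPCAModel-class].
#' @param newdata M x d matrix of points to score (default: the training
#'   set).
#' @param ... unused.
#' @return An M x k score matrix.
#' @export
setGeneric("scores", function(object, newdata, ...) standardGeneric("scores"))

#' @rdname scores
#' @export
setMethod("scores", "KPCAModel", function(object, newdata, ...) {
  if (missing(newdata)) newdata <- object@trainX
  if (is(newdata, "ExpressionDataset")) newdata <- exprMatrix(newdata)
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1L)
  Kc <- if (object@centered)
    crossCenteredKernel(object@trainX, newdata, object@spec,
                        trainRowMeans = object@kRowMeans,
                        trainGrandMean = object@kGrandMean)
  else
    crossKernel(newdata, object@trainX, object@spec)
  Z <- Kc %*% object@alphas
  colnames(Z) <- paste0("PC", seq_len(object@k))
  Z
})

#' Project an ExpressionDataset onto a fitted KPCA model
#'
#' Convenience wrapper returning a new [ExpressionDataset-class] whose
#' features are the k score variables (labels carried through), suitable as
#' classifier input.
#'
#' @param model a [KPCAModel-class].
#' @param data an [ExpressionDataset-class].
#' @return An [ExpressionDataset-class] with k score features.
#' @export
projectDataset <- function(model, data) {
  stopifnot(is(model, "KPCAModel"), is(data, "ExpressionDataset"))
  Z <- scores(model, exprMatrix(data))
  ds <- expressionDataset(Z, data@y, sampleIds = data@sampleIds,
                          featureIds = colnames(Z))
  ds@labelMap <- data@labelMap
  ds
}

#' Serialize / restore a KPCA model
#'
#' Writes the kernel specification, dual coefficients, eigenvalues and kernel
#' centering statistics (plus the training matrix, required for out-of-sample
#' scoring) to a JSON container, and reads it back.
#'
#' @param model a [KPCAModel-class].
#' @param path file path.
#' @return `readKPCAModel` returns the restored [KPCAModel-class].
#' @export
writeKPCAModel <- function(model, path) {
  stopifnot(is(model, "KPCAModel"))
  obj <- list(
    type = "KPCAModel",
    spec = specToList(model@spec),
    trainX = model@trainX,
    alphas = model@alphas,
    eigenvalues = model@eigenvalues,
    k = model@k,
    kRowMeans = model@kRowMeans,
    kGrandMean = model@kGrandMean,
    centered = model@centered)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' @rdname writeKPCAModel
#' @export
readKPCAModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "KPCAModel")) stop("not a KPCAModel container")
  new("KPCAModel", spec = specFromList(obj$spec),
      trainX = as.matrix(obj$trainX), alphas = as.matrix(obj$alphas),
      eigenvalues = as.numeric(obj$eigenvalues), k = as.integer(obj$k),
      kRowMeans = as.numeric(obj$kRowMeans),
      kGrandMean = as.numeric(obj$kGrandMean),
      centered = as.logical(obj$centered))
}

specToList <- function(spec)
  list(family = spec@family, h = spec@h, degree = spec@degree,
       offset = spec@offset)

specFromList <- function(lst)
  new("KernelSpec", family = lst$family,
      h = as.numeric(lst$h %||% NA_real_),
      degree = as.numeric(lst$degree %||% NA_real_),
      offset = as.numeric(lst$offset %||% NA_real_))

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a
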