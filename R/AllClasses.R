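#' @import methods
NULL

# ---------------------------------------------------------------------------
# KernelSpec
# ---------------------------------------------------------------------------

#' Kernel specification
#'
#' Describes a kernel family and its hyperparameters. The RBF kernel is
#' \eqn{K(a,b) = \exp(-\|a-b\|^2 / (2h^2))} with bandwidth \eqn{h > 0} in the
#' same units as the (standardized) features; the linear kernel is the plain
#' inner product; the polynomial kernel is \eqn{(a^T b + c)^p} with offset
#' \eqn{c \ge 0} and integer degree \eqn{p \ge 1}.
#'
#' @slot family character, one of `"rbf"`, `"linear"`, `"polynomial"`.
#' @slot h numeric, RBF bandwidth (unused for other families).
#' @slot degree numeric, polynomial degree.
#' @slot offset numeric, polynomial offset.
#'
#' @seealso [rbfKernel()], [linearKernel()], [polynomialKernel()]
#' @export
setClass("KernelSpec",
  slots = c(family = "character", h = "numeric",
            degree = "numeric", offset = "numeric"),
  prototype = prototype(family = "linear", h = NA_real_,
                        degree = NA_real_, offset = NA_real_))

setValidity("KernelSpec", function(object) {
  msg <- character()
  if (length(object@family) != 1L ||
      !object@family %in% c("rbf", "linear", "polynomial"))
    msg <- c(msg, "family must be one of 'rbf', 'linear', 'polynomial'")
  if (identical(object@family, "rbf") &&
      (length(object@h) != 1L || !is.finite(object@h) || object@h <= 0))
    msg <- c(msg, "rbf kernel requires a finite bandwidth h > 0")
  if (identical(object@family, "polynomial")) {
    if (length(object@degree) != 1L || !is.finite(object@degree) ||
        object@degree < 1 || object@degree != round(object@degree))
      msg <- c(msg, "polynomial kernel requires integer degree >= 1")
    if (length(object@offset) != 1L || !is.finite(object@offset) ||
        object@offset < 0)
      msg <- c(msg, "polynomial kernel requires offset >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Kernel constructors
#'
#' @param h positive RBF bandwidth.
#' @param degree polynomial degree (integer, >= 1).
#' @param offset polynomial offset (>= 0).
#' @return A [KernelSpec-class] object.
#' @examples
#' rbfKernel(2)
#' linearKernel()
#' polynomialKernel(degree = 2)
#' @export
rbfKernel <- function(h) new("KernelSpec", family = "rbf", h = as.numeric(h))

#' @rdname rbfKernel
#' @export
linearKernel <- function() new("KernelSpec", family = "linear")

#' @rdname rbfKernel
#' @export
polynomialKernel <- function(degree = 3, offset = 1)
  new("KernelSpec", family = "polynomial",
      degree = as.numeric(degree), offset = as.numeric(offset))

setMethod("show", "KernelSpec", function(object) {
  desc <- switch(object@family,
    rbf        = sprintf("rbf (h = %g)", object@h),
    linear     = "linear",
    polynomial = sprintf("polynomial (degree = %g, offset = %g)",
                         object@degree, object@offset))
  cat("KernelSpec:", desc, "\n")
  invisible(object)
})

# ---------------------------------------------------------------------------
# ExpressionDataset
# ---------------------------------------------------------------------------

#' Expression dataset container
#'
#' A sample-by-feature numeric matrix with binary class labels coded
#' \{-1, +1\}. Standardization state is carried with the object so the
#' transform learned on a training partition can be inverted, and so that
#' downstream code can assert it is operating on z-score units.
#'
#' @slot X numeric matrix, N samples x d features. No missing values.
#' @slot y numeric length-N vector of labels in \{-1, +1\}.
#' @slot sampleIds character length N.
#' @slot featureIds character length d.
#' @slot standardized logical flag.
#' @slot labelMap character length-2 named vector recording the original label
#'   to \{-1, +1\} mapping (names are original labels, values "-1"/"1").
#' @slot center,scale numeric length-d vectors of the means/SDs used when
#'   standardizing (length 0 when not standardized).
#'
#' @export
setClass("ExpressionDataset",
  slots = c(X = "matrix", y = "numeric",
            sampleIds = "character", featureIds = "character",
            standardized = "logical", labelMap = "character",
            center = "numeric", scale = "numeric"))

setValidity("ExpressionDataset", function(object) {
  msg <- character()
  if (!is.numeric(object@X)) msg <- c(msg, "X must be numeric")
  if (anyNA(object@X)) msg <- c(msg, "X must not contain missing values")
  if (length(object@y) != nrow(object@X))
    msg <- c(msg, "length(y) must equal nrow(X)")
  if (!all(object@y %in% c(-1, 1)))
    msg <- c(msg, "y must be coded in {-1, +1}")
  if (length(object@sampleIds) != nrow(object@X))
    msg <- c(msg, "length(sampleIds) must equal nrow(X)")
  if (length(object@featureIds) != ncol(object@X))
    msg <- c(msg, "length(featureIds) must equal ncol(X)")
  if (length(object@standardized) != 1L)
    msg <- c(msg, "standardized must be a single logical")
  if (isTRUE(object@standardized) &&
      (length(object@center) != ncol(object@X) ||
       length(object@scale) != ncol(object@X)))
    msg <- c(msg, "standardized dataset must carry center/scale per feature")
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionDataset
#'
#' @param X numeric matrix, samples in rows, features in columns.
#' @param y labels: either numeric \{-1, +1\} or any two-level vector (mapped
#'   so the lexicographically smaller level becomes -1).
#' @param sampleIds,featureIds identifier vectors; default to dimnames or
#'   generated ids.
#' @return An [ExpressionDataset-class].
#' @examples
#' d <- expressionDataset(matrix(rnorm(12), 4, 3), c("a", "b", "a", "b"))
#' classLabels(d)
#' @export
expressionDataset <- function(X, y, sampleIds = NULL, featureIds = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(sampleIds))
    sampleIds <- if (!is.null(rownames(X))) rownames(X) else
      paste0("sample", seq_len(nrow(X)))
  if (is.null(featureIds))
    featureIds <- if (!is.null(colnames(X))) colnames(X) else
      paste0("feature", seq_len(ncol(X)))
  mp <- mapLabels(y)
  new("ExpressionDataset", X = X, y = mp$y,
      sampleIds = as.character(sampleIds),
      featureIds = as.character(featureIds),
      standardized = FALSE, labelMap = mp$map,
      center = numeric(0), scale = numeric(0))
}

# Map a two-level label vector to {-1,+1}; lexicographically smaller -> -1.
mapLabels <- function(y) {
  if (is.numeric(y) && all(y %in% c(-1, 1))) {
    map <- c("-1" = "-1", "1" = "1")
    return(list(y = as.numeric(y), map = map))
  }
  y <- as.character(y)
  lev <- sort(unique(y))
  if (length(lev) != 2L)
    stop("labels must have exactly two distinct values, found ",
         length(lev), ": ", paste(utils::head(lev, 5), collapse = ", "))
  map <- stats::setNames(c("-1", "1"), lev)
  list(y = ifelse(y == lev[1L], -1, 1), map = map)
}

setMethod("show", "ExpressionDataset", function(object) {
  cat(sprintf("ExpressionDataset: %d samples x %d features\n",
              nrow(object@X), ncol(object@X)))
  cat(sprintf("  classes: %d (-1) / %d (+1)%s\n",
              sum(object@y == -1), sum(object@y == 1),
              if (object@standardized) ", standardized" else ""))
  invisible(object)
})

#' Accessors for ExpressionDataset
#'
#' @param object an [ExpressionDataset-class].
#' @return `exprMatrix` the samples x features matrix; `classLabels` the
#'   \{-1,+1\} label vector; `sampleIds`/`featureIds` identifier vectors;
#'   `isStandardized` the standardization flag.
#' @export
setGeneric("exprMatrix", function(object) standardGeneric("exprMatrix"))

#' @rdname exprMatrix
#' @export
setMethod("exprMatrix", "ExpressionDataset", function(object) object@X)

#' @rdname exprMatrix
#' @export
setGeneric("classLabels", function(object) standardGeneric("classLabels"))

#' @rdname exprMatrix
#' @export
setMethod("classLabels", "ExpressionDataset", function(object) object@y)

#' @rdname exprMatrix
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))

#' @rdname exprMatrix
#' @export
setMethod("sampleIds", "ExpressionDataset", function(object) object@sampleIds)

#' @rdname exprMatrix
#' @export
setGeneric("featureIds", function(object) standardGeneric("featureIds"))

#' @rdname exprMatrix
#' @export
setMethod("featureIds", "ExpressionDataset", function(object) object@featureIds)

#' @rdname exprMatrix
#' @export
setGeneric("isStandardized", function(object) standardGeneric("isStandardized"))

#' @rdname exprMatrix
#' @export
setMethod("isStandardized", "ExpressionDataset",
          function(object) object@standardized)

#' @describeIn exprMatrix number of samples / features.
#' @export
setMethod("dim", "ExpressionDataset", function(x) dim(x@X))

#' Subset an ExpressionDataset by sample index
#'
#' @param x an [ExpressionDataset-class].
#' @param i sample indices.
#' @param j,...,drop ignored (features are never subset; kernel methods need
#'   the full feature vector).
#' @export
setMethod("[", "ExpressionDataset", function(x, i, j, ..., drop = FALSE) {
  initialize(x, X = x@X[i, , drop = FALSE], y = x@y[i],
             sampleIds = x@sampleIds[i])
})

# ---------------------------------------------------------------------------
# SplitPlan
# ---------------------------------------------------------------------------

#' Stratified train/test split plan
#'
#' @slot trainIdx,testIdx disjoint integer index vectors covering all samples.
#' @slot seed integer seed that generated the split.
#' @slot fraction training fraction in (0, 1).
#' @export
setClass("SplitPlan",
  slots = c(trainIdx = "integer", testIdx = "integer",
            seed = "integer", fraction = "numeric"))

setValidity("SplitPlan", function(object) {
  msg <- character()
  if (length(intersect(object@trainIdx, object@testIdx)))
    msg <- c(msg, "train and test indices must be disjoint")
  if (length(object@fraction) != 1L || object@fraction <= 0 ||
      object@fraction >= 1)
    msg <- c(msg, "fraction must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SplitPlan", function(object) {
  cat(sprintf("SplitPlan: %d train / %d test (fraction %.3f, seed %d)\n",
              length(object@trainIdx), length(object@testIdx),
              object@fraction, object@seed))
  invisible(object)
})

# ---------------------------------------------------------------------------
# KPCAModel
# ---------------------------------------------------------------------------

#' Fitted kernel PCA model
#'
#' Holds the top-k eigenpairs of the centered Gram matrix
#' \eqn{\Omega_c \alpha = \lambda \alpha}, plus the training data and kernel
#' centering statistics needed to score out-of-sample points with the same
#' centered feature map.
#'
#' @slot spec the [KernelSpec-class] used.
#' @slot trainX N x d training matrix (retained for scoring).
#' @slot alphas N x k matrix of dual coefficient eigenvectors, unit Euclidean
#'   norm columns, sign-fixed so each column's largest-magnitude entry is
#'   positive.
#' @slot eigenvalues length-k, non-increasing, (numerically) non-negative.
#' @slot k integer, retained components.
#' @slot kRowMeans length-N row means of the uncentered training kernel matrix.
#' @slot kGrandMean grand mean of the uncentered training kernel matrix.
#' @slot centered logical; TRUE when the eigenproblem was posed on the
#'   double-centered Gram matrix (the default).
#' @export
setClass("KPCAModel",
  slots = c(spec = "KernelSpec", trainX = "matrix", alphas = "matrix",
            eigenvalues = "numeric", k = "integer",
            kRowMeans = "numeric", kGrandMean = "numeric",
            centered = "logical"))

setValidity("KPCAModel", function(object) {
  msg <- character()
  if (ncol(object@alphas) != object@k)
    msg <- c(msg, "alphas must have k columns")
  if (nrow(object@alphas) != nrow(object@trainX))
    msg <- c(msg, "alphas must have one row per training sample")
  if (length(object@eigenvalues) != object@k)
    msg <- c(msg, "eigenvalues must have length k")
  if (object@k > 0) {
    nrm <- sqrt(colSums(object@alphas^2))
    if (any(abs(nrm - 1) > 1e-6))
      msg <- c(msg, "alpha columns must have unit Euclidean norm")
    if (is.unsorted(rev(object@eigenvalues), strictly = FALSE))
      msg <- c(msg, "eigenvalues must be non-increasing")
    if (any(object@eigenvalues < -1e-8 * max(object@eigenvalues[1], 1e-300)))
      msg <- c(msg, "eigenvalues must be non-negative up to tolerance")
  }
  if (length(object@kRowMeans) != nrow(object@trainX))
    msg <- c(msg, "kRowMeans must have one entry per training sample")
  if (length(msg)) msg else TRUE
})

setMethod("show", "KPCAModel", function(object) {
  cat(sprintf("KPCAModel: %d components on %d samples\n",
              object@k, nrow(object@trainX)))
  show(object@spec)
  if (object@k > 0)
    cat("  eigenvalues:",
        paste(signif(utils::head(object@eigenvalues, 5), 4), collapse = ", "),
        if (object@k > 5) "..." else "", "\n")
  invisible(object)
})

#' Eigenvalues of a fitted KPCA model
#' @param object a [KPCAModel-class].
#' @export
setGeneric("eigenvalues", function(object) standardGeneric("eigenvalues"))

#' @rdname eigenvalues
#' @export
setMethod("eigenvalues", "KPCAModel", function(object) object@eigenvalues)

#' Dual coefficient matrix (alpha eigenvectors) of a fitted KPCA model
#' @param object a [KPCAModel-class].
#' @export
setGeneric("dualCoef", function(object) standardGeneric("dualCoef"))

#' @rdname dualCoef
#' @export
setMethod("dualCoef", "KPCAModel", function(object) object@alphas)

#' Kernel specification of a fitted model
#' @param object a fitted [KPCAModel-class] or [LSSVMModel-class].
#' @export
setGeneric("kernelSpec", function(object) standardGeneric("kernelSpec"))

#' @rdname kernelSpec
#' @export
setMethod("kernelSpec", "KPCAModel", function(object) object@spec)

# ---------------------------------------------------------------------------
# SelectionSurface
# ---------------------------------------------------------------------------

#' Model-selection criterion surface
#'
#' The leave-one-out criterion J evaluated on a bandwidth x components grid,
#' with the selected bandwidth (surface argmax) and component count
#' (elbow rule on the marginal gains).
#'
#' @slot hGrid positive bandwidths (a single NA row for linear PCA surfaces).
#' @slot kGrid integer component counts.
#' @slot J |hGrid| x |kGrid| criterion matrix, non-negative, non-decreasing
#'   along k; optionally rescaled to maximum 1.
#' @slot hHat,kHat selected bandwidth and component count.
#' @slot cvMode "loo" or "vfold".
#' @slot v number of folds when cvMode is "vfold".
#' @slot rescaled logical; TRUE when J was divided by its maximum.
#' @export
setClass("SelectionSurface",
  slots = c(hGrid = "numeric", kGrid = "integer", J = "matrix",
            hHat = "numeric", kHat = "integer",
            cvMode = "character", v = "integer", rescaled = "logical"))

setValidity("SelectionSurface", function(object) {
  msg <- character()
  if (nrow(object@J) != length(object@hGrid) ||
      ncol(object@J) != length(object@kGrid))
    msg <- c(msg, "J must be |hGrid| x |kGrid|")
  if (any(object@J < -1e-12))
    msg <- c(msg, "J must be non-negative")
  if (!object@cvMode %in% c("loo", "vfold"))
    msg <- c(msg, "cvMode must be 'loo' or 'vfold'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SelectionSurface", function(object) {
  cat(sprintf("SelectionSurface: %d bandwidths x %d component counts (%s)\n",
              length(object@hGrid), length(object@kGrid),
              if (object@cvMode == "vfold")
                sprintf("%d-fold CV", object@v) else "leave-one-out"))
  cat(sprintf("  selected: h = %s, k = %d%s\n",
              if (is.na(object@hHat)) "NA (linear)" else
                format(signif(object@hHat, 6)),
              object@kHat,
              if (object@rescaled) " (J rescaled to max 1)" else ""))
  invisible(object)
})

#' Selected bandwidth / component count of a SelectionSurface
#' @param object a [SelectionSurface-class].
#' @export
setGeneric("selectedBandwidth",
           function(object) standardGeneric("selectedBandwidth"))

#' @rdname selectedBandwidth
#' @export
setMethod("selectedBandwidth", "SelectionSurface",
          function(object) object@hHat)

#' @rdname selectedBandwidth
#' @export
setGeneric("selectedComponents",
           function(object) standardGeneric("selectedComponents"))

#' @rdname selectedBandwidth
#' @export
setMethod("selectedComponents", "SelectionSurface",
          function(object) object@kHat)

#' Criterion matrix of a SelectionSurface
#' @param object a [SelectionSurface-class].
#' @export
setGeneric("criterionValues",
           function(object) standardGeneric("criterionValues"))

#' @rdname criterionValues
#' @export
setMethod("criterionValues", "SelectionSurface", function(object) {
  J <- object@J
  dimnames(J) <- list(h = signif(object@hGrid, 6), k = object@kGrid)
  J
})

# ---------------------------------------------------------------------------
# LSSVMModel
# ---------------------------------------------------------------------------

#' Fitted least-squares SVM classifier
#'
#' Dual solution of the bordered linear system
#' \deqn{\left[\begin{array}{cc} 0 & y^T \\ y & \Omega + I/\gamma
#' \end{array}\right] \left[\begin{array}{c} b \\ \beta \end{array}\right] =
#' \left[\begin{array}{c} 0 \\ 1_N \end{array}\right]}
#' with \eqn{\Omega_{ij} = y_i y_j K(x_i, x_j)}.
#'
#' @slot betas length-N Lagrange multipliers.
#' @slot b bias term.
#' @slot gamma positive regularization constant.
#' @slot spec the classifier [KernelSpec-class].
#' @slot trainX,trainY training inputs and \{-1,+1\} labels (retained for
#'   prediction).
#' @export
setClass("LSSVMModel",
  slots = c(betas = "numeric", b = "numeric", gamma = "numeric",
            spec = "KernelSpec", trainX = "matrix", trainY = "numeric"))

setValidity("LSSVMModel", function(object) {
  msg <- character()
  if (length(object@betas) != nrow(object@trainX))
    msg <- c(msg, "betas must have one entry per training sample")
  if (length(object@trainY) != nrow(object@trainX))
    msg <- c(msg, "trainY must have one entry per training sample")
  if (length(object@gamma) != 1L || object@gamma <= 0)
    msg <- c(msg, "gamma must be a single positive value")
  if (length(msg)) msg else TRUE
})

setMethod("show", "LSSVMModel", function(object) {
  cat(sprintf("LSSVMModel: %d training samples, gamma = %g, b = %g\n",
              nrow(object@trainX), object@gamma, object@b))
  show(object@spec)
  invisible(object)
})

#' @rdname kernelSpec
#' @export
setMethod("kernelSpec", "LSSVMModel", function(object) object@spec)

# ---------------------------------------------------------------------------
# SyntheticSpec
# ---------------------------------------------------------------------------

#' Synthetic dataset specification
#'
#' Parameters of the microarray-like generator: a low-dimensional latent class
#' structure is embedded into d ambient features through a seeded random
#' orthonormal map, and independent Gaussian noise is added to every feature.
#'
#' @slot nPerClass samples per class.
#' @slot d ambient feature count.
#' @slot informativeDim latent dimension carrying class structure.
#' @slot structure `"linear-shift"`, `"radial"`, or `"two-moons"`.
#' @slot effect class separation in latent units (shift distance, shell radius
#'   gap, or moon scale).
#' @slot noiseSd ambient Gaussian noise standard deviation (> 0).
#' @slot seed integer seed; generation is fully deterministic given the spec.
#' @export
setClass("SyntheticSpec",
  slots = c(nPerClass = "integer", d = "integer", informativeDim = "integer",
            structure = "character", effect = "numeric", noiseSd = "numeric",
            seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (object@informativeDim < 1L || object@d < object@informativeDim)
    msg <- c(msg, "need d >= informativeDim >= 1")
  if (!object@structure %in% c("linear-shift", "radial", "two-moons"))
    msg <- c(msg, "structure must be 'linear-shift', 'radial' or 'two-moons'")
  if (object@effect < 0) msg <- c(msg, "effect must be >= 0")
  if (object@noiseSd <= 0) msg <- c(msg, "noiseSd must be > 0")
  if (object@nPerClass < 2L) msg <- c(msg, "need at least 2 samples per class")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    "SyntheticSpec: %s, 2 x %d samples, %d features (%d informative latent)\n",
    object@structure, object@nPerClass, object@d, object@informativeDim))
  cat(sprintf("  effect = %g, noise sd = %g, seed = %d\n",
              object@effect, object@noiseSd, object@seed))
  invisible(object)
})

# ---------------------------------------------------------------------------
# EvaluationReport
# ---------------------------------------------------------------------------

#' Repeated-split evaluation report
#'
#' @slot method label of the evaluated pipeline.
#' @slot auc per-repeat test AUC (NA where a repeat failed).
#' @slot params data.frame of selected (h, k, gamma) per repeat.
#' @slot seeds per-repeat derived seeds.
#' @slot meanAUC,sdAUC summaries over completed repeats.
#' @slot repeats configured number of repeats.
#' @slot failures character vector of per-repeat failure reasons ("" if ok).
#' @export
setClass("EvaluationReport",
  slots = c(method = "character", auc = "numeric", params = "data.frame",
            seeds = "integer", meanAUC = "numeric", sdAUC = "numeric",
            repeats = "integer", failures = "character"))

setValidity("EvaluationReport", function(object) {
  msg <- character()
  if (length(object@auc) != object@repeats)
    msg <- c(msg, "auc must have one entry per configured repeat")
  ok <- !is.na(object@auc)
  if (any(ok)) {
    if (abs(object@meanAUC - mean(object@auc[ok])) > 1e-12)
      msg <- c(msg, "stored meanAUC does not match per-repeat values")
    sdv <- if (sum(ok) > 1) stats::sd(object@auc[ok]) else 0
    if (abs(object@sdAUC - sdv) > 1e-12)
      msg <- c(msg, "stored sdAUC does not match per-repeat values")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "EvaluationReport", function(object) {
  ok <- sum(!is.na(object@auc))
  cat(sprintf("EvaluationReport: %s\n", object@method))
  cat(sprintf("  test AUC %.4f (sd %.4f) over %d/%d repeats\n",
              object@meanAUC, object@sdAUC, ok, object@repeats))
  invisible(object)
})
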