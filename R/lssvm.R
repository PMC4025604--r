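# Least-squares SVM binary classifier in the dual: one bordered (N+1) x
# (N+1) linear system, latent decision values, and seeded grid tuning of the
# regularization constant (and classifier bandwidth for RBF kernels).

#' Fit an LS-SVM classifier
#'
#' Solves the dual saddle-point system
#' \deqn{\left[\begin{array}{cc} 0 & y^T \\ y & \Omega + I/\gamma
#' \end{array}\right]\left[\begin{array}{c} b \\ \beta\end{array}\right] =
#' \left[\begin{array}{c} 0 \\ 1_N\end{array}\right], \quad
#' \Omega_{ij} = y_i y_j K(x_i, x_j),}
#' by a dense factorization of the full bordered matrix. The first row
#' enforces \eqn{y^T\beta = 0}. A numerically singular system (pathological
#' duplicates at extreme \eqn{\gamma}) falls back to a least-squares solve
#' with a warning.
#'
#' @param X numeric M x p matrix of inputs (raw features or score
#'   variables), or an [ExpressionDataset-class] (labels then taken from it).
#' @param y labels in \{-1, +1\} (ignored when `X` is an ExpressionDataset).
#' @param spec classifier [KernelSpec-class].
#' @param gamma positive regularization constant.
#' @return An [LSSVMModel-class].
#' @export
fitLSSVM <- function(X, y = NULL, spec = linearKernel(), gamma = 1) {
  if (is(X, "ExpressionDataset")) {
    y <- classLabels(X)
    X <- exprMatrix(X)
  }
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) stop("labels must be coded in {-1, +1}")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (gamma <= 0) stop("gamma must be positive")
  N <- nrow(X)
  K <- gramMatrix(X, spec)
  Omega <- (y %o% y) * K
  A <- rbind(c(0, y), cbind(y, Omega + diag(N) / gamma))
  rhs <- c(0, rep(1, N))
  sol <- tryCatch(solve(A, rhs), error = function(e) {
    warning("bordered system numerically singular; using least squares")
    stats::lsfit(A, rhs, intercept = FALSE)$coefficients
  })
  sol <- unname(sol)
  new("LSSVMModel", betas = sol[-1L], b = sol[1L], gamma = gamma,
      spec = spec, trainX = X, trainY = y)
}

#' Latent decision values of an LS-SVM
#'
#' Returns \eqn{\sum_k \beta_k y_k K(x, x_k) + b}, the argument of the sign
#' in the classifier; [predictLabels()] applies the sign, and AUC uses the
#' latent value as the ranking score.
#'
#' @param object an [LSSVMModel-class].
#' @param newdata M x p matrix of points (default: the training set).
#' @param ... unused.
#' @return Numeric vector of latent values.
#' @export
setGeneric("decisionValues",
           function(object, newdata, ...) standardGeneric("decisionValues"))

#' @rdname decisionValues
#' @export
setMethod("decisionValues", "LSSVMModel", function(object, newdata, ...) {
  if (missing(newdata)) newdata <- object@trainX
  if (is(newdata, "ExpressionDataset")) newdata <- exprMatrix(newdata)
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1L)
  if (ncol(newdata) != ncol(object@trainX))
    stop("test points have ", ncol(newdata), " features; model expects ",
         ncol(object@trainX))
  Kx <- crossKernel(newdata, object@trainX, object@spec)
  as.numeric(Kx %*% (object@betas * object@trainY) + object@b)
})

#' @rdname decisionValues
#' @export
setGeneric("predictLabels",
           function(object, newdata, ...) standardGeneric("predictLabels"))

#' @rdname decisionValues
#' @export
setMethod("predictLabels", "LSSVMModel", function(object, newdata, ...) {
  v <- decisionValues(object, newdata, ...)
  ifelse(v >= 0, 1, -1)
})

#' Residual of the fitted bordered system
#'
#' Relative residual of the (N+1)-dimensional saddle system at the fitted
#' solution; a solver contract check (should be <= 1e-8 on well-posed
#' problems).
#'
#' @param model an [LSSVMModel-class].
#' @return A non-negative scalar.
#' @export
lssvmResidual <- function(model) {
  stopifnot(is(model, "LSSVMModel"))
  y <- model@trainY
  N <- length(y)
  K <- gramMatrix(model@trainX, model@spec)
  A <- rbind(c(0, y), cbind(y, (y %o% y) * K + diag(N) / model@gamma))
  sol <- c(model@b, model@betas)
  rhs <- c(0, rep(1, N))
  sqrt(sum((A %*% sol - rhs)^2)) / sqrt(sum(rhs^2))
}

#' Tune LS-SVM hyperparameters by stratified cross-validated AUC
#'
#' Grid search over the regularization constant \eqn{\gamma} (and, for RBF
#' classifier kernels, jointly over the kernel bandwidth), scored by mean
#' validation AUC over stratified folds. Ties are broken toward smaller
#' \eqn{\gamma} (stronger regularization), then smaller bandwidth.
#' Deterministic given the seed. A fold that loses a class is re-drawn with
#' a new derived seed, at most 5 attempts.
#'
#' @param X numeric matrix or [ExpressionDataset-class].
#' @param y labels in \{-1, +1\}.
#' @param spec classifier [KernelSpec-class]; for `family = "rbf"` the slot
#'   `h` is ignored and tuned instead.
#' @param gammaGrid positive values; default 13 log-spaced points in
#'   10^-3..10^3.
#' @param hGrid bandwidth grid for RBF kernels; defaults to
#'   [defaultBandwidthGrid()] with 7 points.
#' @param folds number of CV folds (>= 2).
#' @param seed integer seed.
#' @return list with elements `gamma`, `h` (NA unless RBF), `cvAUC`, and
#'   `spec` (the tuned [KernelSpec-class]).
#' @export
tuneGamma <- function(X, y = NULL, spec = linearKernel(),
                      gammaGrid = 10^seq(-3, 3, length.out = 13),
                      hGrid = NULL, folds = 10L, seed = 1L) {
  if (is(X, "ExpressionDataset")) {
    y <- classLabels(X)
    X <- exprMatrix(X)
  }
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (folds < 2L) stop("folds must be >= 2")
  if (!length(gammaGrid)) stop("gammaGrid must be nonempty")
  tuneH <- identical(spec@family, "rbf")
  if (tuneH && is.null(hGrid))
    hGrid <- defaultBandwidthGrid(X, length = 7L)
  hVals <- if (tuneH) sort(hGrid) else NA_real_
  fold <- stratifiedFolds(y, folds, seed)
  best <- list(auc = -Inf, gamma = NA_real_, h = NA_real_)
  for (h in hVals) {
    sp <- if (tuneH) rbfKernel(h) else spec
    for (g in sort(gammaGrid)) {
      aucs <- vapply(seq_len(max(fold)), function(f) {
        tr <- fold != f
        m <- fitLSSVM(X[tr, , drop = FALSE], y[tr], sp, g)
        aucScore(decisionValues(m, X[!tr, , drop = FALSE]), y[!tr])
      }, numeric(1))
      a <- mean(aucs)
      if (a > best$auc + 1e-12) best <- list(auc = a, gamma = g, h = h)
    }
  }
  sp <- if (tuneH) rbfKernel(best$h) else spec
  list(gamma = best$gamma, h = if (tuneH) best$h else NA_real_,
       cvAUC = best$auc, spec = sp)
}

# Stratified fold labels; refolds with a derived seed (at most 5 attempts)
# if any fold ends up with only one class in its training part.
stratifiedFolds <- function(y, folds, seed) {
  folds <- min(folds, min(table(y)))
  if (folds < 2L) stop("too few samples per class for cross-validation")
  for (attempt in 0:4) {
    rng <- localRNG(seed + attempt)
    fold <- integer(length(y))
    for (cl in unique(y)) {
      idx <- rng$permute(which(y == cl))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
    ok <- all(vapply(seq_len(folds), function(f)
      length(unique(y[fold != f])) == 2L, logical(1)))
    if (ok) return(fold)
  }
  stop("could not build folds with both classes in every training part")
}

#' Serialize / restore an LS-SVM model
#'
#' JSON container mirroring [writeKPCAModel()], so a full pipeline
#' (selection, projection, classifier) round-trips from disk.
#'
#' @param model an [LSSVMModel-class].
#' @param path file path.
#' @return `readLSSVMModel` returns the restored [LSSVMModel-class].
#' @export
writeLSSVMModel <- function(model, path) {
  stopifnot(is(model, "LSSVMModel"))
  obj <- list(type = "LSSVMModel", spec = specToList(model@spec),
              betas = model@betas, b = model@b, gamma = model@gamma,
              trainX = model@trainX, trainY = model@trainY)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' @rdname writeLSSVMModel
#' @export
readLSSVMModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "LSSVMModel")) stop("not an LSSVMModel container")
  new("LSSVMModel", betas = as.numeric(obj$betas), b = as.numeric(obj$b),
      gamma = as.numeric(obj$gamma), spec = specFromList(obj$spec),
      trainX = as.matrix(obj$trainX), trainY = as.numeric(obj$trainY))
}
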