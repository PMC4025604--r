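# Experimental harness: rank-based AUC, repeated stratified-split protocol,
# and the exact Wilcoxon signed-rank comparison between paired AUC series.

#' Area under the ROC curve (Mann-Whitney rank formulation)
#'
#' \eqn{AUC = (R_+ - n_+(n_+ + 1)/2) / (n_+ n_-)} where \eqn{R_+} is the
#' midrank sum of the positive-class scores: the probability that a random
#' positive outranks a random negative, ties counting 1/2.
#'
#' @param scoreValues numeric ranking scores (larger = more positive).
#' @param labels labels in \{-1, +1\} (or any two-level vector; the
#'   lexicographically larger level is the positive class).
#' @return AUC in \[0, 1\].
#' @examples
#' aucScore(c(1, 2, 3, 4), c(-1, 1, -1, 1))  # 0.75
#' @export
aucScore <- function(scoreValues, labels) {
  if (length(scoreValues) != length(labels))
    stop("scores and labels must have the same length")
  y <- mapLabels(labels)$y
  nPos <- sum(y == 1)
  nNeg <- sum(y == -1)
  if (nPos == 0 || nNeg == 0) stop("both classes must be present")
  r <- rank(scoreValues)  # midranks on ties
  (sum(r[y == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Two-sided Wilcoxon signed-rank test for paired series
#'
#' Zero differences are dropped (Wilcoxon's original treatment). With no
#' ties among the absolute differences and at most 25 non-zero pairs, the
#' exact null distribution of the positive-rank sum is used; otherwise the
#' normal approximation with continuity correction and the midrank tie
#' correction of the variance.
#'
#' @param a,b paired numeric vectors of equal length.
#' @return list with `p.value`, `statistic` (positive-rank sum W), `n`
#'   (non-zero pairs) and `method` ("exact" or "normal").
#' @examples
#' signedRankTest(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1))$p.value  # 0.0625
#' @export
signedRankTest <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all differences are zero; p = 1")
    return(list(p.value = 1, statistic = 0, n = 0L, method = "degenerate"))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- any(duplicated(r))
  if (!ties && n <= 25L) {
    p <- 2 * min(stats::psignrank(W, n),
                 stats::psignrank(W - 1, n, lower.tail = FALSE))
    return(list(p.value = min(p, 1), statistic = W, n = n,
                method = "exact"))
  }
  mu <- n * (n + 1) / 4
  tieTab <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tieTab^3 - tieTab) / 48
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
  list(p.value = min(2 * stats::pnorm(-abs(z)), 1), statistic = W, n = n,
       method = "normal")
}

#' Repeated stratified-split evaluation protocol
#'
#' For each repeat: stratified 2/3-1/3 split, standardization fitted on the
#' training partition and applied to both, optional dimensionality reduction
#' selected on the training partition only (bandwidth and component count by
#' the leave-one-out criterion for KPCA, component count for PCA), classifier
#' hyperparameters tuned by stratified CV on the training partition, LS-SVM
#' fit, test-set AUC from the latent decision values. Test labels are never
#' touched before the final AUC. All randomness derives from the master seed;
#' repeats are independent.
#'
#' @param data an [ExpressionDataset-class] on the original scale.
#' @param method `"whole"`, `"pca"` or `"kpca"` (the preprocessing).
#' @param classifierKernel classifier [KernelSpec-class]; default linear.
#'   For RBF, its bandwidth is tuned per repeat.
#' @param repeats number of random train/test splits (default 30).
#' @param seed master seed.
#' @param fraction training fraction (default 2/3).
#' @param hGrid bandwidth grid for KPCA selection (default:
#'   [defaultBandwidthGrid()] of the training partition).
#' @param kMax largest component count for selection (default
#'   `min(Ntrain - 2, 15)`).
#' @param gammaGrid,tuneFolds passed to [tuneGamma()].
#' @param selectionCV `"loo"` or `"vfold"` for the selection criterion.
#' @param standardizeOn `"train"` (leakage-safe default) or `"all"`
#'   (whole-data standardization, for strict reproduction attempts).
#' @return An [EvaluationReport-class].
#' @export
runProtocol <- function(data, method = c("kpca", "pca", "whole"),
                        classifierKernel = linearKernel(),
                        repeats = 30L, seed = 1L, fraction = 2 / 3,
                        hGrid = NULL, kMax = NULL,
                        gammaGrid = 10^seq(-3, 3, length.out = 13),
                        tuneFolds = 10L, selectionCV = NULL,
                        standardizeOn = c("train", "all")) {
  stopifnot(is(data, "ExpressionDataset"))
  method <- match.arg(method)
  standardizeOn <- match.arg(standardizeOn)
  repeats <- as.integer(repeats)
  repeatSeeds <- deriveSeeds(seed, repeats)
  aucs <- rep(NA_real_, repeats)
  params <- data.frame(h = rep(NA_real_, repeats), k = NA_integer_,
                       gamma = NA_real_, classifierH = NA_real_)
  failures <- character(repeats)
  for (r in seq_len(repeats)) {
    res <- tryCatch(
      oneRepeat(data, method, classifierKernel, repeatSeeds[r], fraction,
                hGrid, kMax, gammaGrid, tuneFolds, selectionCV,
                standardizeOn),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failures[r] <- res
    } else {
      aucs[r] <- res$auc
      params$h[r] <- res$h
      params$k[r] <- res$k
      params$gamma[r] <- res$gamma
      params$classifierH[r] <- res$classifierH
    }
  }
  ok <- !is.na(aucs)
  if (!any(ok)) stop("all repeats failed; first reason: ", failures[1L])
  label <- sprintf("%s+lssvm(%s)", method, classifierKernel@family)
  new("EvaluationReport", method = label, auc = aucs, params = params,
      seeds = repeatSeeds, meanAUC = mean(aucs[ok]),
      sdAUC = if (sum(ok) > 1) stats::sd(aucs[ok]) else 0,
      repeats = repeats, failures = failures)
}

# Integer repeat seeds derived deterministically from the master seed
# (kept below 2^31).
deriveSeeds <- function(seed, n) {
  rng <- localRNG(seed)
  as.integer(vapply(seq_len(n), function(i)
    floor(rng$runif(1) * (2^31 - 2)) + 1, numeric(1)))
}

oneRepeat <- function(data, method, classifierKernel, seed, fraction,
                      hGrid, kMax, gammaGrid, tuneFolds, selectionCV,
                      standardizeOn) {
  plan <- stratifiedSplit(data, fraction, seed)
  ref <- if (standardizeOn == "train") plan@trainIdx else
    seq_len(nrow(exprMatrix(data)))
  std <- suppressWarnings(standardizeDataset(data, ref))
  train <- std[plan@trainIdx]
  test <- std[plan@testIdx]
  h <- NA_real_
  k <- NA_integer_
  if (method != "whole") {
    nTr <- nrow(exprMatrix(train))
    kM <- if (is.null(kMax)) min(nTr - 2L, 15L) else min(kMax, nTr - 2L)
    if (method == "kpca") {
      surf <- selectBandwidthAndK(train, hGrid = hGrid, kMax = kM,
                                  cv = selectionCV, seed = seed)
      h <- surf@hHat
      k <- surf@kHat
      model <- fitKPCA(train, rbfKernel(h), k)
    } else {
      surf <- selectPCAComponents(train, kMax = kM, cv = selectionCV,
                                  seed = seed)
      k <- surf@kHat
      model <- fitLinearPCA(train, k)
    }
    train <- projectDataset(model, train)
    test <- projectDataset(model, test)
  }
  tuned <- tuneGamma(train, spec = classifierKernel, gammaGrid = gammaGrid,
                     folds = tuneFolds, seed = seed)
  clf <- fitLSSVM(train, spec = tuned$spec, gamma = tuned$gamma)
  vals <- decisionValues(clf, exprMatrix(test))
  list(auc = aucScore(vals, classLabels(test)), h = h, k = k,
       gamma = tuned$gamma, classifierH = tuned$h)
}

#' Per-repeat results of an EvaluationReport
#'
#' @param object an [EvaluationReport-class].
#' @return A data.frame with one row per repeat: seed, AUC, selected h, k,
#'   gamma, classifier bandwidth, and failure reason (empty when completed).
#' @export
setGeneric("repeatResults", function(object) standardGeneric("repeatResults"))

#' @rdname repeatResults
#' @export
setMethod("repeatResults", "EvaluationReport", function(object) {
  cbind(data.frame(seed = object@seeds, auc = object@auc),
        object@params, failure = object@failures)
})

#' Write an evaluation report
#'
#' Per-repeat results as delimited text plus a JSON summary (method, mean/sd
#' AUC, repeats, completeness).
#'
#' @param report an [EvaluationReport-class].
#' @param path base path; `<path>.tsv` and `<path>.json` are written.
#' @export
writeReport <- function(report, path) {
  stopifnot(is(report, "EvaluationReport"))
  utils::write.table(repeatResults(report), paste0(path, ".tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(method = report@method, mean_auc = report@meanAUC,
         sd_auc = report@sdAUC, repeats = report@repeats,
         completed = sum(!is.na(report@auc))),
    paste0(path, ".json"), digits = NA, auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' Compare two evaluation reports by signed-rank test
#'
#' Two-sided Wilcoxon signed-rank test on the paired per-repeat AUC series
#' of two reports run with the same master seed (hence identical splits).
#'
#' @param a,b [EvaluationReport-class] objects with equal repeat counts.
#' @return As [signedRankTest()].
#' @export
compareReports <- function(a, b) {
  stopifnot(is(a, "EvaluationReport"), is(b, "EvaluationReport"))
  if (a@repeats != b@repeats)
    stop("reports have different numbers of repeats")
  if (!identical(a@seeds, b@seeds))
    warning("reports were not run with the same master seed; ",
            "pairs are not matched splits")
  ok <- !is.na(a@auc) & !is.na(b@auc)
  signedRankTest(a@auc[ok], b@auc[ok])
}
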