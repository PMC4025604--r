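# Loading, validation, standardization and stratified splitting of
# expression datasets.

#' Load an expression dataset from delimited text
#'
#' Reads a samples-in-rows table with a header of feature identifiers and one
#' label column holding exactly two distinct values. The delimiter is taken
#' from the file extension (`.csv` comma, `.tsv`/`.txt` tab; `.gz` variants
#' are read transparently) unless given explicitly. Labels are mapped to
#' \{-1, +1\} with the lexicographically smaller original label becoming -1;
#' the mapping is recorded in the returned object.
#'
#' @param path file path.
#' @param labelColumn name of the label column.
#' @param delimiter optional delimiter override.
#' @param transpose set TRUE for gene-by-sample files (table is transposed
#'   after reading; the label column is then expected in the transposed
#'   orientation, i.e. one labels row).
#' @return An [ExpressionDataset-class] with `standardized = FALSE`.
#' @export
loadDataset <- function(path, labelColumn = "class", delimiter = NULL,
                        transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delimiter)) {
    base <- sub("\\.gz$", "", path)
    delimiter <- if (grepl("\\.csv$", base, ignore.case = TRUE)) "," else "\t"
  }
  tab <- utils::read.table(path, header = TRUE, sep = delimiter,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           row.names = NULL)
  if (transpose) {
    rn <- tab[[1L]]
    tab <- as.data.frame(t(as.matrix(tab[, -1L, drop = FALSE])),
                         stringsAsFactors = FALSE)
    colnames(tab) <- rn
  }
  if (!labelColumn %in% colnames(tab))
    stop("label column '", labelColumn, "' not found; columns are: ",
         paste(utils::head(colnames(tab), 8), collapse = ", "))
  yRaw <- tab[[labelColumn]]
  feat <- tab[, setdiff(colnames(tab), labelColumn), drop = FALSE]
  X <- suppressWarnings(
    vapply(feat, function(col) as.numeric(col), numeric(nrow(feat))))
  X <- matrix(X, nrow = nrow(feat),
              dimnames = list(NULL, colnames(feat)))
  bad <- which(is.na(X), arr.ind = TRUE)
  if (nrow(bad)) {
    cells <- apply(utils::head(bad, 10), 1L, function(rc)
      sprintf("row %d, column '%s'", rc[1L], colnames(X)[rc[2L]]))
    stop("missing or non-numeric values at: ",
         paste(cells, collapse = "; "),
         if (nrow(bad) > 10) sprintf(" (and %d more)", nrow(bad) - 10) else "")
  }
  if (length(unique(as.character(yRaw))) < 2L)
    stop("label column '", labelColumn, "' has a single class; ",
         "two classes are required")
  expressionDataset(X, yRaw,
                    sampleIds = paste0("sample", seq_len(nrow(X))),
                    featureIds = colnames(X))
}

#' Write an ExpressionDataset to delimited text
#'
#' Inverse of [loadDataset()]: samples in rows, a header of feature ids and a
#' label column. Labels are written using the recorded original labels so a
#' round trip preserves the \{-1,+1\} coding.
#'
#' @param data an [ExpressionDataset-class].
#' @param path output path (`.csv` or `.tsv` decide the delimiter).
#' @param labelColumn label column name.
#' @export
writeDataset <- function(data, path, labelColumn = "class") {
  stopifnot(is(data, "ExpressionDataset"))
  delimiter <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  inv <- stats::setNames(names(data@labelMap), data@labelMap)
  lab <- inv[as.character(data@y)]
  tab <- data.frame(data@X, check.names = FALSE)
  colnames(tab) <- data@featureIds
  tab[[labelColumn]] <- lab
  utils::write.table(tab, path, sep = delimiter, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Standardize features to zero mean and unit variance
#'
#' Each feature is shifted and scaled by the mean and standard deviation
#' computed on the reference samples only (typically the training partition,
#' so no information leaks from test samples); the same affine transform is
#' applied to all samples. The population SD convention (divide by n) is the
#' default so reference features have variance exactly 1 in the population
#' sense; the sample convention (n - 1) is available.
#'
#' A feature that is constant on the reference set is centered and left
#' unscaled, with a warning.
#'
#' @param data an [ExpressionDataset-class].
#' @param referenceIndices sample indices defining the transform (default:
#'   all samples).
#' @param sdType `"population"` (divide by n) or `"sample"` (n - 1).
#' @return A standardized [ExpressionDataset-class] carrying the transform.
#' @seealso [inverseStandardize()]
#' @export
standardizeDataset <- function(data, referenceIndices = seq_len(nrow(data@X)),
                               sdType = c("population", "sample")) {
  stopifnot(is(data, "ExpressionDataset"))
  sdType <- match.arg(sdType)
  if (!length(referenceIndices)) stop("reference set must be nonempty")
  ref <- data@X[referenceIndices, , drop = FALSE]
  n <- nrow(ref)
  ctr <- colMeans(ref)
  dev <- sweep(ref, 2L, ctr)
  ss <- colSums(dev^2)
  scl <- sqrt(ss / if (sdType == "population") n else max(n - 1L, 1L))
  const <- scl < .Machine$double.eps^0.5 * pmax(abs(ctr), 1)
  if (any(const)) {
    warning(sum(const), " feature(s) constant on the reference set; ",
            "centered but left unscaled")
    scl[const] <- 1
  }
  Xs <- sweep(sweep(data@X, 2L, ctr), 2L, scl, "/")
  initialize(data, X = Xs, standardized = TRUE, center = ctr, scale = scl)
}

#' Invert a standardization
#'
#' Recovers the original expression units from a standardized dataset using
#' the means and SDs stored at standardization time.
#'
#' @param data a standardized [ExpressionDataset-class].
#' @return The dataset on the original scale, `standardized = FALSE`.
#' @export
inverseStandardize <- function(data) {
  stopifnot(is(data, "ExpressionDataset"))
  if (!data@standardized) stop("dataset is not standardized")
  X <- sweep(sweep(data@X, 2L, data@scale, "*"), 2L, data@center, "+")
  initialize(data, X = X, standardized = FALSE,
             center = numeric(0), scale = numeric(0))
}

#' Stratified train/test split
#'
#' Assigns a fraction of each class to the training set, so the class
#' proportions of both partitions match the full data up to rounding. The
#' per-class training counts are `floor(fraction * classSize)`, and any
#' deficit against `round(fraction * N)` is resolved by adding samples to the
#' larger classes first. Deterministic given the seed.
#'
#' @param data an [ExpressionDataset-class]; every class needs >= 2 samples.
#' @param fraction training fraction in (0, 1); default 2/3.
#' @param seed integer seed.
#' @return A [SplitPlan-class].
#' @export
stratifiedSplit <- function(data, fraction = 2 / 3, seed = 1L) {
  stopifnot(is(data, "ExpressionDataset"))
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must be strictly between 0 and 1")
  y <- data@y
  sizes <- table(y)
  if (any(sizes < 2L))
    stop("every class needs at least 2 samples to split")
  base <- floor(fraction * as.numeric(sizes))
  base <- pmin(pmax(base, 1L), as.numeric(sizes) - 1L)
  deficit <- round(fraction * length(y)) - sum(base)
  if (deficit > 0) {
    ord <- order(as.numeric(sizes), decreasing = TRUE)
    for (cl in rep_len(ord, 10L * length(sizes))) {
      if (deficit <= 0) break
      if (base[cl] < sizes[cl] - 1L) {
        base[cl] <- base[cl] + 1L
        deficit <- deficit - 1L
      }
    }
  }
  rng <- localRNG(seed)
  trainIdx <- integer(0)
  for (ci in seq_along(sizes)) {
    idx <- which(y == as.numeric(names(sizes))[ci])
    trainIdx <- c(trainIdx, rng$sampleInt(idx, base[ci]))
  }
  trainIdx <- sort(trainIdx)
  new("SplitPlan", trainIdx = as.integer(trainIdx),
      testIdx = setdiff(seq_along(y), trainIdx),
      seed = as.integer(seed), fraction = fraction)
}

# Seed-local RNG helper: draws without disturbing the caller's RNG state.
localRNG <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, envir = globalenv())
  use <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
        assign(".Random.seed", old, envir = globalenv())
    })
    f()
  }
  list(
    sampleInt = function(x, size) use(function() {
      if (length(x) == 1L) x else sample(x, size)
    }),
    runif = function(n) use(function() stats::runif(n)),
    rnorm = function(n, sd = 1) use(function() stats::rnorm(n, sd = sd)),
    permute = function(x) use(function() sample(x, length(x)))
  )
}
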