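# Independent oracles, written with explicit loops and no shared code with
# the package implementation.

# Longhand criterion surface J(h, k): for each bandwidth and each held-out
# sample, build the reduced RBF kernel matrix entry by entry, apply the
# four-term centering formula term by term, eigendecompose, score all N
# samples through the centered cross-kernel, and accumulate unit-spaced
# trapezoidal integrals of the absolute scores.
longhandSurface <- function(X, hGrid, kMax) {
  N <- nrow(X)
  J <- matrix(0, length(hGrid), kMax)
  for (hi in seq_along(hGrid)) {
    h <- hGrid[hi]
    kf <- function(a, b) exp(-sum((a - b)^2) / (2 * h^2))
    perComp <- numeric(kMax)
    for (j in seq_len(N)) {
      idx <- setdiff(seq_len(N), j)
      M <- length(idx)
      K <- matrix(0, M, M)
      for (p in seq_len(M)) for (q in seq_len(M))
        K[p, q] <- kf(X[idx[p], ], X[idx[q], ])
      Kc <- matrix(0, M, M)
      for (p in seq_len(M)) for (q in seq_len(M))
        Kc[p, q] <- K[p, q] - sum(K[p, ]) / M - sum(K[q, ]) / M +
          sum(K) / M^2
      eg <- eigen(Kc, symmetric = TRUE)
      rank <- sum(eg$values > 1e-12)
      for (n in seq_len(min(kMax, rank))) {
        z <- numeric(N)
        for (t in seq_len(N)) {
          kt <- numeric(M)
          for (i in seq_len(M)) kt[i] <- kf(X[t, ], X[idx[i], ])
          acc <- 0
          for (i in seq_len(M)) {
            ktc <- kt[i] - sum(kt) / M - sum(K[i, ]) / M + sum(K) / M^2
            acc <- acc + ktc * eg$vectors[i, n]
          }
          z[t] <- acc
        }
        az <- abs(z)
        integ <- 0
        for (t in seq_len(N - 1L)) integ <- integ + (az[t] + az[t + 1L]) / 2
        perComp[n] <- perComp[n] + integ
      }
    }
    tot <- 0
    for (n in seq_len(kMax)) {
      tot <- tot + perComp[n]
      J[hi, n] <- tot / N
    }
  }
  J
}

# AUC by exhaustive positive-negative pair counting (ties count 1/2).
bruteForceAUC <- function(scoreValues, y) {
  pos <- which(y == 1)
  neg <- which(y == -1)
  wins <- 0
  for (p in pos) for (q in neg) {
    if (scoreValues[p] > scoreValues[q]) wins <- wins + 1
    else if (scoreValues[p] == scoreValues[q]) wins <- wins + 0.5
  }
  wins / (length(pos) * length(neg))
}

# Small seeded random dataset (matrix + balanced-ish labels).
randomDataset <- function(N, d, seed) {
  set.seed(seed)
  X <- matrix(rnorm(N * d), N, d)
  y <- rep(c(-1, 1), length.out = N)
  expressionDataset(X, y)
}
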