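# Seeded generator of microarray-like two-class datasets: a low-dimensional
# latent class structure embedded into many ambient features through a random
# orthonormal map, plus independent Gaussian noise everywhere. Gives every
# other module a testable input without external downloads.

#' Build a synthetic dataset specification
#'
#' Defaults emulate a small two-class expression study: 2 x 20 samples,
#' 200 features carrying a 2-dimensional latent structure, ambient noise sd
#' 0.1 (so the embedded signal, of order `effect`, dominates each informative
#' ambient direction). A paper-scale preset (N = 100, d = 10000) is available
#' through the arguments.
#'
#' Structures: `"linear-shift"` — both classes standard normal in the latent
#' space, class +1 shifted by `effect` along the first latent axis;
#' `"radial"` — concentric shells, class -1 on radius 1 and class +1 on
#' radius `1 + effect`, directions uniform on the latent sphere (the class is
#' a deterministic function of the latent radius, so no linear projection
#' separates the classes); `"two-moons"` — the interleaved half-circle pair
#' scaled by `effect`, embedded from its 2-dimensional plane.
#'
#' @param nPerClass samples per class.
#' @param d ambient features.
#' @param informativeDim latent dimension (2 for `"two-moons"`).
#' @param structure `"linear-shift"`, `"radial"` or `"two-moons"`.
#' @param effect class separation in latent units.
#' @param noiseSd ambient noise sd (> 0).
#' @param seed integer seed.
#' @return A [SyntheticSpec-class].
#' @export
syntheticSpec <- function(nPerClass = 20L, d = 200L, informativeDim = 2L,
                          structure = c("radial", "linear-shift", "two-moons"),
                          effect = 2, noiseSd = 0.1, seed = 1L) {
  structure <- match.arg(structure)
  if (structure == "two-moons") informativeDim <- 2L
  new("SyntheticSpec", nPerClass = as.integer(nPerClass), d = as.integer(d),
      informativeDim = as.integer(informativeDim), structure = structure,
      effect = as.numeric(effect), noiseSd = as.numeric(noiseSd),
      seed = as.integer(seed))
}

#' Generate a synthetic expression dataset
#'
#' Draws latent points per the spec's structure, embeds them into d ambient
#' dimensions through an orthonormal map (Q factor of a seeded Gaussian
#' matrix), and adds independent Gaussian noise to every feature. The d -
#' informativeDim directions orthogonal to the embedding carry pure noise.
#' Fully deterministic given the spec (the caller's RNG state is untouched).
#'
#' @param spec a [SyntheticSpec-class].
#' @return An [ExpressionDataset-class] with labels "neg" (-1) / "pos" (+1).
#' @examples
#' generateDataset(syntheticSpec(nPerClass = 10, d = 50, seed = 7))
#' @export
generateDataset <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec@seed)

  n <- spec@nPerClass
  m <- spec@informativeDim
  y <- rep(c(-1, 1), each = n)
  L <- switch(spec@structure,
    "linear-shift" = {
      L0 <- matrix(stats::rnorm(2 * n * m), 2 * n, m)
      L0[y == 1, 1L] <- L0[y == 1, 1L] + spec@effect
      L0
    },
    "radial" = {
      U <- matrix(stats::rnorm(2 * n * m), 2 * n, m)
      U <- U / sqrt(rowSums(U^2))
      radius <- ifelse(y == 1, 1 + spec@effect, 1)
      U * radius
    },
    "two-moons" = {
      t1 <- stats::runif(n, 0, pi)
      t2 <- stats::runif(n, 0, pi)
      upper <- cbind(cos(t1), sin(t1))
      lower <- cbind(1 - cos(t2), 0.5 - sin(t2))
      rbind(upper, lower) * spec@effect
    })
  Q <- qr.Q(qr(matrix(stats::rnorm(spec@d * m), spec@d, m)))
  X <- L %*% t(Q) +
    matrix(stats::rnorm(2 * n * spec@d, sd = spec@noiseSd), 2 * n, spec@d)
  labels <- ifelse(y == 1, "pos", "neg")
  expressionDataset(X, labels,
                    sampleIds = paste0("sample", seq_len(2 * n)),
                    featureIds = paste0("feature", seq_len(spec@d)))
}
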