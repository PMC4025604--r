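# kpcaTune

Dimensionality reduction and classification for high-dimensional
(features ≫ samples) two-class expression data, built around a
**data-driven, unsupervised selection criterion for the RBF kernel PCA
bandwidth `h` and component count `k`**.

Kernel PCA is a powerful preprocessing step for expression classifiers —
it can unfold nonlinear class structure that linear PCA cannot — but it is
unsupervised, so its two hyperparameters cannot be tuned against a
classification loss without coupling the reduction to a particular
classifier. This package selects them from the data alone.

## The method

Kernel PCA solves the dual eigenproblem on the double-centered Gram matrix

```
Ω_c α = λ α,    Ω_c,ij = K(x_i,x_j) − (1/N)Σ_r K(x_i,x_r)
                          − (1/N)Σ_r K(x_j,x_r) + (1/N²)Σ_{r,s} K(x_r,x_s)
```

with the RBF kernel `K(a,b) = exp(−‖a−b‖² / 2h²)`. The score of a point
`x` on component `n` is `z_n(x) = Σ_i α_i⁽ⁿ⁾ K_c(x_i, x)`. The selection
criterion maximizes the leave-one-out absolute projected signal

```
J(h,k) = (1/N) Σ_{n=1..k} Σ_{j=1..N} ∫ |z_n^(−j)(x)| dx
```

where `z_n^(−j)` is the score function of a model fitted with sample `j`
left out, and the integral is evaluated by the trapezoidal rule over the
absolute scores at all `N` samples. The held-out construction is what
makes the criterion honest: a component only scores well if it
generalizes. `h` is the grid argmax; since `J` is non-decreasing in `k`,
`k` is picked by an elbow rule on the marginal gains. Downstream, a
least-squares SVM — one bordered linear system

```
[ 0  yᵀ        ] [b]   [0 ]
[ y  Ω + I/γ   ] [β] = [1_N],   Ω_ij = y_i y_j K(x_i,x_j)
```

— classifies the projected data, with `γ` tuned by stratified
cross-validated AUC. A repeated stratified-split harness (30× 2/3–1/3 by
default) reports mean/sd test AUC and compares methods pairwise with the
exact Wilcoxon signed-rank test. See the vignette
(`vignettes/kpca-bandwidth-selection.Rmd`) for the assumptions, the
integration-rule and elbow-rule design decisions, and limitations.

## Worked example

Concentric shells — a radial two-class structure in a 2-dimensional latent
space embedded in 200 noisy features — are invisible to linear projections
but separable after a well-tuned kernel PCA:

```r
library(kpcaTune)

d <- generateDataset(syntheticSpec(nPerClass = 20, d = 200,
                                   structure = "radial", effect = 2,
                                   noiseSd = 0.1, seed = 1))
d
#> ExpressionDataset: 40 samples x 200 features
#>   classes: 20 (-1) / 20 (+1)

s <- standardizeDataset(d)
surf <- selectBandwidthAndK(s, kMax = 10, seed = 1)
surf
#> SelectionSurface: 30 bandwidths x 10 component counts (leave-one-out)
#>   selected: h = 10.7257, k = 10 (J rescaled to max 1)

model <- fitKPCA(s, rbfKernel(selectedBandwidth(surf)),
                 selectedComponents(surf))
round(eigenvalues(model), 2)
#>  [1] 3.41 3.20 2.11 1.59 1.20 0.81 0.78 0.75 0.75 0.70

kpca <- runProtocol(d, "kpca", repeats = 10, seed = 7, kMax = 10)
pca  <- runProtocol(d, "pca",  repeats = 10, seed = 7, kMax = 10)
kpca
#> EvaluationReport: kpca+lssvm(linear)
#>   test AUC 0.9976 (sd 0.0075) over 10/10 repeats
pca
#> EvaluationReport: pca+lssvm(linear)
#>   test AUC 0.4738 (sd 0.0988) over 10/10 repeats
compareReports(kpca, pca)$p.value
#> [1] 0.005793048
```

The selected bandwidth (≈ 10.7 here) sits near the median pairwise
distance of the standardized data — the scale at which the RBF kernel
resolves the shells. The KPCA pipeline reaches test AUC ≈ 1 while linear
PCA stays at chance, and the paired signed-rank test confirms the gap on
the shared splits.

Real datasets load from delimited text (samples in rows, one label
column): `loadDataset("expr.csv", labelColumn = "class")`. A thin CLI over
the same functions lives at `inst/cli/kpca-tool.R` (subcommands `select`,
`project`, `train`, `evaluate`, `compare`).

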