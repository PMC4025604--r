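---
title: "Selecting the kernel PCA bandwidth and component count by leave-one-out projected variance"
author: "kpcaTune"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting the kernel PCA bandwidth and component count}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kpcaTune)
```

## The problem

Expression studies routinely produce matrices with a few dozen to a few
hundred samples and thousands to tens of thousands of features. Classifiers
built directly on such matrices are unstable, so some dimensionality
reduction is applied first. Kernel PCA with an RBF kernel is an attractive
*unsupervised* reduction — it can unfold nonlinear class structure that
linear PCA cannot — but it has two free parameters, the bandwidth $h$ and
the number of retained components $k$, and because the method never sees
class labels there is no obvious loss to tune them against. This package
implements a data-driven selection criterion for $(h, k)$ based on
leave-one-out cross-validation of the projected variance, together with the
surrounding pipeline: kernel PCA itself, a least-squares SVM (LS-SVM)
classifier, an evaluation harness, and a synthetic-data generator.

## Kernel PCA as a least-squares SVM problem

For training samples $x_1,\dots,x_N \in \mathbb{R}^d$ and a feature map
$\varphi$, kernel PCA maximizes the variance of the projections
$e_i = v^T(\varphi(x_i) - \hat\mu_\varphi)$ subject to a ridge penalty on
$v$. Eliminating the primal variables yields the dual eigenproblem

$$\Omega_c\,\alpha = \lambda\,\alpha,\qquad
\Omega_{c,ij} = K(x_i,x_j) - \tfrac1N\sum_r K(x_i,x_r)
- \tfrac1N\sum_r K(x_j,x_r) + \tfrac1{N^2}\sum_{r,s}K(x_r,x_s),$$

the eigendecomposition of the double-centered Gram matrix. The RBF kernel
is $K(a,b) = \exp(-\|a-b\|^2/(2h^2))$ — note the $2h^2$ denominator, a
common source of $\sqrt2$ drift between implementations. The score of a
point $x$ on component $n$ is $z_n(x) = \sum_i \alpha_i^{(n)} K_c(x_i, x)$,
where $K_c$ is the centered (cross-)kernel. Linear PCA is the linear-kernel
special case: the eigenvalues of $\Omega_c$ then equal the squared singular
values of the column-centered data matrix. `fitKPCA()`, `scores()` and
`fitLinearPCA()` implement exactly this; the dense symmetric eigensolver is
appropriate because $N$ is at most a few hundred in this regime.

Two conventions had to be fixed where the mathematics leaves a free scale:

* **Eigenvector normalization.** The dual eigenvectors $\alpha^{(n)}$ are
  returned with unit Euclidean norm (the plain symmetric-eigenproblem
  convention), which makes the training scores equal
  $\lambda_n\alpha^{(n)}$. Any fixed rescaling applied uniformly across the
  bandwidth grid leaves the selection argmax unchanged, so this choice is
  harmless downstream (tested).
* **Sign.** Each column's largest-magnitude entry is made positive. The
  criterion uses $|z_n|$ and the classifier re-tunes, so signs are
  irrelevant scientifically; fixing them removes eigensolver
  nondeterminism.
* **Centering for linear PCA.** The linear branch runs on the *centered*
  Gram matrix, keeping the two code paths identical; the plain-Gram
  formulation is available with `centered = FALSE`.

## The selection criterion

The criterion scores a bandwidth by how much absolute projected signal its
score functions carry when evaluated out-of-sample:

$$J(h,k) \;=\; \frac1N \sum_{n=1}^{k}\sum_{j=1}^{N}
\int \bigl|z_n^{(-j)}(x)\bigr|\,dx,$$

where $z_n^{(-j)}$ is the $n$-th score function of a model fitted with
sample $j$ left out. The leave-one-out construction is what prevents the
trivial overfit: evaluated in-sample, larger $h$ is always "better",
whereas a held-out sample only projects strongly if the component
generalizes. The selected bandwidth $\hat h$ maximizes the criterion over
a grid.

Two aspects of this definition are genuinely open and were resolved as
package design choices:

* **The integral.** $\int|z_n(x)|\,dx$ has no defined domain or measure for
  $d$-dimensional $x$. We evaluate $|z_n^{(-j)}|$ at all $N$ training
  samples, in canonical dataset order, and apply the unit-spaced
  trapezoidal rule to that vector (equivalently, the L1 norm of the score
  vector minus half the two endpoint values). This uses the empirical
  sample measure as the integration proxy, is comparable across bandwidths
  because the evaluation points are held fixed, and reduces the rule to
  simple, order-stable arithmetic. Evaluating only the left-out point would
  collapse the integral to a single value and cannot drive a quadrature
  rule. `looScoreIntegral()` exposes one $(n, j)$ term.
* **Choosing $k$.** $J(h,k)$ is a sum of non-negative per-component
  integrals, hence non-decreasing in $k$; its raw argmax over $k$ is always
  the largest $k$ on the grid. We therefore select $k$ by an elbow rule:
  the smallest $k$ whose *next* marginal gain $J(h, k+1)-J(h,k)$ falls
  below a fraction $\varepsilon$ (default 0.01) of the largest marginal
  gain at the selected bandwidth. The full surface is always returned
  (`criterionValues()`), so any other rule can be applied by the user.

Remaining defaults, all overridable: the bandwidth grid is 30
log-spaced points from $0.1\times$ to $10\times$ the median pairwise
Euclidean distance of the (standardized) samples — the range over which the
RBF Gram matrix transitions from nearly diagonal to nearly constant;
leave-one-out is replaced by seeded 10-fold CV when $N > 150$ (cost is one
refit per held-out group per grid point); the surface is rescaled to
maximum 1 for plotting, which cannot move the argmax (tested). Components
beyond the numerical rank of a held-out fit (eigenvalues below $10^{-12}$)
contribute zero, with a warning. Non-finite criterion entries are set to 0
with a warning rather than poisoning the argmax.

The linear-PCA component selector `selectPCAComponents()` is the same
machinery restricted to the linear kernel, producing a one-row surface over
$k$ only.

```{r selection-demo}
d <- generateDataset(syntheticSpec(nPerClass = 15, d = 60,
                                   structure = "radial", effect = 2,
                                   noiseSd = 0.1, seed = 1))
s <- standardizeDataset(d)
surf <- selectBandwidthAndK(s, kMax = 6, seed = 1)
surf
```

## The LS-SVM classifier

The downstream classifier is the least-squares SVM: squared-error slacks
turn the usual SVM quadratic program into one linear system

$$\begin{bmatrix} 0 & y^T \\ y & \Omega + I/\gamma \end{bmatrix}
\begin{bmatrix} b \\ \beta \end{bmatrix} =
\begin{bmatrix} 0 \\ 1_N \end{bmatrix},\qquad
\Omega_{ij} = y_i y_j K(x_i, x_j),$$

with classifier $\hat y(x) = \mathrm{sign}\bigl(\sum_k \beta_k y_k
K(x, x_k) + b\bigr)$. We solve the full bordered system by a dense
factorization — at $N \le$ a few hundred there is nothing to gain from
elimination tricks, and the single solve makes the contract checkable: the
relative residual must be at machine precision and the first row enforces
$y^T\beta = 0$ exactly. Ranking (AUC) uses the latent value, not the sign.
$\gamma$ — and for RBF classifiers the kernel bandwidth — is tuned by
stratified 10-fold CV maximizing validation AUC (matching AUC reporting),
ties broken toward stronger regularization. The tuning protocol is this
package's own: upstream tooling for LS-SVMs leaves it unspecified, so
per-dataset results from other implementations are comparable only
approximately.

## The evaluation protocol

`runProtocol()` mirrors the standard small-sample design: stratified
2/3–1/3 splits repeated 30 times (defaults), each repeat re-doing the whole
pipeline from scratch on its training partition — standardization
(population-SD z-scores), $(h,k)$ selection, projection, $\gamma$ tuning,
fit — and only then touching test labels to compute the Mann–Whitney
rank AUC. All randomness derives from one master seed, so two methods run
with the same seed see identical splits and can be compared pairwise by the
exact Wilcoxon signed-rank test (`compareReports()`; exact null for up to
25 tie-free non-zero differences via the signed-rank distribution, normal
approximation with continuity and tie corrections otherwise, zero
differences dropped).

Two leakage questions are ambiguous in common practice and are settled
leakage-safe by default, with the permissive mode available for strict
reproduction of published pipelines: standardization statistics come from
the training partition only (`standardizeOn = "all"` switches to
whole-data), and $(h,k)$ are re-selected inside every repeat rather than
once globally.

## What the synthetic generator emulates

`generateDataset()` produces two-class sample-by-feature matrices shaped
like small expression studies: an `informativeDim`-dimensional latent class
structure (a mean shift, concentric shells, or two moons) is embedded into
`d` ambient features through a random orthonormal map drawn once per seed
(QR factor of a seeded Gaussian matrix), and independent Gaussian noise is
added everywhere, so the $d - m$ directions orthogonal to the embedding are
pure noise. The radial structure is the motivating case for kernel PCA: the
class is a deterministic function of latent radius, so no linear projection
separates it, while an RBF kernel at a bandwidth near the data scale does.

Defaults are deliberately small ($2\times20$ samples, $d = 200$,
latent dimension 2, shells at radius 1 and 3, noise sd 0.1) so the full
pipeline runs in seconds; the same generator produces paper-scale shapes
($N \approx 100$, $d \approx 10^4$) by changing the arguments. The noise
level keeps the per-feature signal standard deviation
($\approx$ effect $\times\sqrt{m/d} \approx 0.2$–0.3) above the noise sd,
which models the situation where many correlated features carry the
biology; after per-feature standardization the latent geometry then
survives. What the generator does **not** emulate: batch effects,
intensity-dependent variance, heavy-tailed noise, or correlated noise
between features. Passing tests on these fixtures therefore demonstrate
the machinery and its selection behavior, not performance claims on real
microarray data.

## Numerical choices and degenerate inputs

* Population-SD standardization (divide by $n$), so reference features have
  variance exactly 1 in the stated sense; sample convention available.
  Constant reference features are centered, left unscaled, and warned
  about.
* Centered Gram matrices are symmetrized after construction; asymmetry
  beyond $10^{-8}$ in user-supplied kernels is an error, not repaired.
* Eigenvalue floor $10^{-12}$ for rank decisions; eigensolver noise in
  $[-10^{-8}\lambda_1, 0)$ is clamped to 0.
* Ties in eigenvalues are ordered by the eigensolver; within an eigenspace
  the choice is arbitrary and documented as such (the criterion is
  invariant because it sums over the tied components' integrals).
* A numerically singular LS-SVM system (duplicate points at extreme
  $\gamma$) falls back to least squares with a warning.
* Splits require at least two samples per class; CV folds that lose a
  class are re-drawn with a derived seed, at most five attempts.

## Problem sizes

The shipped tests and the acceptance script run entirely on generated
data at the sizes the defaults encode: oracle comparisons at $N \le 8$
against an explicit-loop reimplementation of the whole criterion
(agreement to $10^{-9}$ relative), bandwidth-recovery and
shell-separation studies at $N = 30$–40, $d = 60$–200 with 10–20
replicates, and grids of 20–30 bandwidths. A full
`selectBandwidthAndK()` at $N = 40$ costs $N$ eigendecompositions of
$(N-1)$-sized matrices per grid point and runs in well under a second;
the complete repeated-split protocol on the shell fixture takes a few
seconds.

## Known limitations

* The criterion is defined for the RBF family; it is not applied to
  polynomial kernels (no bandwidth to select, and the integral proxy has
  only been studied for the RBF case here).
* The elbow rule for $k$ is an interpretation forced by the monotonicity
  of $J$ in $k$; different $\varepsilon$ give different $k$ on flat
  spectra. The surface is returned so this choice is auditable.
* The trapezoid-over-score-vector integral is a documented reading of an
  underdetermined definition, not established fact; an alternative
  (sorting abscissae by the leading component's scores) would weight
  samples differently, though the bandwidth argmax is empirically stable
  between such readings on the shipped fixtures.
* Leave-one-out selection costs $O(N)$ eigendecompositions per grid point;
  beyond a few hundred samples use the v-fold mode.
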