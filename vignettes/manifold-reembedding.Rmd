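---
title: "Manifold re-embedding of word vectors: model, parameters, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Manifold re-embedding of word vectors: model, parameters, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wordmlle)
```

## The problem

Pre-trained word vectors (word2vec, GloVe) place words in a
high-dimensional Euclidean space, but the semantic structure they encode
is widely believed to concentrate near a curved low-dimensional manifold.
Straight-line (cosine or Euclidean) comparisons then suffer a systematic
bias: two points on different "folds" of the manifold can be close through
the ambient space while being far apart along it. In clinical text this
shows up as term pairs whose embedding similarity contradicts human
relatedness judgments. `wordmlle` post-processes such embeddings: it
learns the local manifold structure from a sample of the vocabulary with
Modified Locally Linear Embedding (MLLE) and re-expresses every word in
the learned coordinate system, where distances follow the manifold.

## The model

### Local reconstruction weights

Given training vectors $x_1,\dots,x_n \in \mathbb{R}^D$, each point $i$
receives a neighborhood $J_i$ of size $k$ and a family of $s_i$
sum-to-one weight vectors minimizing the reconstruction cost

$$\min \sum_{i=1}^{n} \sum_{l=1}^{s_i}
  \Big\| x_i - \sum_{j \in J_i} w^{(l)}_{j,i}\, x_j \Big\|^2 .$$

Let $C_i$ be the $k \times D$ matrix of centered neighbors
$x_j - x_i$ and $G_i = C_i C_i^\top$ its Gram matrix. MLLE stabilizes
plain LLE by using *multiple* linearly independent weight vectors per
point, built from the subspace spanned by the eigenvectors $V_i$
($k \times s_i$) of $G_i$ for its $s_i$ smallest eigenvalues:

$$w_i^{(l)} = (1 - \alpha_i)\, w_i(\gamma) + V_i H_i(:, l),
  \qquad l = 1, \dots, s_i,$$

where $w_i(\gamma)$ is the single ridge-regularized barycentric solution
of $(G_i + \gamma I) w = \mathbf{1}$ normalized to sum one,
$v_i = V_i^\top \mathbf{1}$, $\alpha_i = \lVert v_i\rVert / \sqrt{s_i}$,
and $H_i$ is the Householder reflection mapping $v_i$ to
$\alpha_i \mathbf{1}$. The reflection makes every column sum to one
($\mathbf{1}^\top V_i H_i(:,l) = (H_i v_i)_l = \alpha_i$), which is the
constraint that renders the final embedding translation-invariant.

### The embedding

Scattering the weight columns into $n$-dimensional index space gives the
alignment matrix
$\Phi = \sum_i \sum_l (e_i - \tilde W_i^{(l)})(e_i - \tilde W_i^{(l)})^\top$,
a symmetric PSD matrix with $\Phi \mathbf{1} = 0$. The embedded
coordinates $Y$ ($n \times d$) are the eigenvectors of $\Phi$ for its
$d$ smallest nonzero eigenvalues; the constant eigenvector is discarded,
and each column's sign is fixed so its largest-magnitude entry is
positive (a pure reporting convention — the cost is sign-blind).

### Geodesic neighbor selection

Neighborhoods are chosen in two stages. A Euclidean $k_{\text{graph}}$-NN
graph (edge weight = Euclidean distance, symmetrized) supports
shortest-path distances $f(x_i, x_j)$, the Isomap-style approximation of
distance along the manifold. These are normalized to

$$d_{ij} = \frac{f(x_i, x_j)}{\sqrt{d(x_i)\, d(x_j)}},$$

where $d(x_i)$ is the mean geodesic distance of $x_i$ to all other
points, making the metric invariant under uniform rescaling of the
coordinates and comparable between dense and sparse regions. The final
$J_i$ are the $k$ points with smallest $d_{ij}$ (ties broken toward the
smaller index). The Euclidean-kNN stage is unavoidable — geodesics
presuppose a graph — so this two-stage reading is the minimal consistent
one; `neighbor_metric = "euclidean"` skips the geodesic stage entirely
and reproduces the classical MLLE neighborhood rule (this is also the
mode compared against an independent reference implementation in the
test suite). Pairs split across disconnected graph components fall back
to their ambient Euclidean distance with a logged message: dropping
points would silently change the sample, and infinite distances would
poison the normalization.

### Window sampling

For word vectors the model is fitted not on the whole vocabulary but on
a contiguous *window* of the frequency-ranked vocabulary
(`select_window()`): frequent words sample the underlying manifold
densely, and the $O(n^2)$ distance machinery stays tractable. Frequency
ranks default to file row order (standard releases are frequency-sorted)
and can be overridden by a `word<TAB>count` side file. Typical window
sizes are 1001–2001 words with start offsets up to 1000; the defaults
(`window size 1001`, `k = 500`, `d = D`) mirror the settings explored in
the accompanying parameter studies. Both the start and the size are
exposed because neither is canonically fixed.

### Out-of-sample extension

A new vector $x$ is embedded by finding its $k_{\text{oos}}$ nearest
training points under the Euclidean metric (a novel point is outside the
geodesic graph; attaching it would require a Euclidean hop anyway),
solving the same ridge-regularized sum-to-one least squares for weights
$w$ — weights of non-neighbors are zero — and mapping
$y = \sum_j w_j\, y_j$. This is the closed-form minimizer of the
single-point embedding cost, exactly linear in $Y$ and
translation-equivariant. Although the training objective uses multiple
weight vectors per point, any family of out-of-sample weight vectors
averages to this same minimizer, so a single regularized vector loses
nothing. Words inside the training window pass through to their fitted
coordinates by default (`training = "passthrough"`), making re-embedding
idempotent on the window; `"transform"` re-computes them like any other
word for users who prefer a uniform treatment.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `k` | 500 | neighborhood size for the local weights (unitless count) |
| `d` | input dimension `D` | embedding dimension; `d = D` re-expresses vectors between two equally-dimensional coordinate systems |
| `k_graph` | `k` | neighbors used to build the geodesic support graph |
| `gamma_scale` | `1e-3` | ridge scale, relative to `trace(G_i)` |
| `eta` | `1e-3` | relative energy threshold splitting each local spectrum; `"auto"` uses the adaptive median-ratio rule |
| `k_oos` | `k` | out-of-sample neighborhood size |

Notes on the less obvious ones:

* **`eta` and $s_i$.** $s_i$ is the largest $t$ such that the trailing
  energy ratio
  $\sum_{\text{last } t} \sigma^2 / \sum_{\text{first } k-t} \sigma^2$
  stays below `eta`, clamped to $[1, \max(1, k - d)]$. The clamp keeps at
  least one weight vector per point even when $k \le d$, where the
  nominal MLLE range $[1, k-d]$ is empty; the fit warns in that regime
  because the method then degenerates to single-weight regularized LLE.
  A spectrum whose values are all equal (including the all-zero
  degenerate neighborhood) carries no large/small information and takes
  the upper clamp. `eta = "auto"` instead sets the threshold to the
  median over points of the energy ratio beyond the first $d$ values —
  the adaptive rule used by reference implementations, and the setting
  under which this package agrees with them to numerical precision.
* **`gamma_scale`.** The ridge makes $(G_i + \gamma I)$ invertible when
  $k > \operatorname{rank}(C_i)$, at the price of an $O(\gamma)$ bias in
  the weights and an $O(\gamma^2)$ floor in the embedding cost. On
  noiseless data that lies exactly on a $d$-dimensional subspace the
  method recovers the latent coordinates *exactly* only in the
  $\gamma \to 0$ limit; the recovery checks in the test suite therefore
  run at `gamma_scale = 1e-8`, while `1e-3` remains the sensible default
  for noisy data.

## Numerical choices

* Eigen-decomposition is dense (`eigen(symmetric = TRUE)`): the intended
  window sizes (≤ ~2000 points) make an $n \times n$ solve cheap and
  avoid sparse-solver convergence contingencies. Likewise the $O(n^2)$
  distance storage (~32 MB at $n = 2001$) is accepted deliberately.
* Shortest paths use Dijkstra on the symmetrized kNN graph; zero-weight
  edges (duplicate points) are legal.
* Local spectra zero out eigenvalues beyond
  $\operatorname{rank}(C_i) \le \min(k, D)$ before the ratio tests, so
  round-off junk in the structural null space cannot distort $s_i$.
* Determinism: the fit involves no randomness; generators accept a seed
  and restore the caller's RNG state; OOV vectors hash the word into a
  seeded stream so the same word always gets the same vector.

## What the synthetic generator emulates — and what it does not

`simulate_manifold_embeddings()` reproduces the method's core premise:
points near a curved 2-manifold (swiss roll, S-curve) or a linear
subspace, lifted into high dimension by a random orthogonal map
(norm-preserving, so the noise scale keeps its meaning), plus isotropic
Gaussian noise. The returned latent coordinates are isometric (arc-length
parameterization), so latent Euclidean distance equals geodesic distance
along the noiseless surface — the ground truth for evaluation.
`generate_similarity_gold()` rates sampled pairs by a strictly monotone
exponential decay of latent distance, which is exactly what a
rank-correlation evaluation needs, and
`generate_zipf_frequencies()` supplies a frequency-sorted vocabulary.

What this does **not** emulate: real embedding spaces have unknown,
varying intrinsic dimension, anisotropic and heteroscedastic noise,
polysemy (one point for several senses), and human ratings that are
noisy and non-monotone in any single geometric quantity. Passing the
synthetic suite shows the machinery is correct and that the method
refines similarity when its geometric premise holds; it does not show
that any particular clinical corpus satisfies that premise.

## Operating regimes and known limitations

* **Well-posed regime ($k > d$, adequate density).** The test suite's
  end-to-end property uses a 900-word vocabulary with a 600-word window,
  $k = 20 > d = 5$, and a sparse support graph
  ($k_{\text{graph}} = 10$): neighborhoods stay within one winding of
  the roll, the fit unrolls, and both distance- and cosine-based
  rank agreement with the latent geometry improve decisively over the
  ambient space. These sizes were chosen as the smallest that sample the
  standard swiss roll densely enough for 10-NN balls to respect the
  winding gap.
* **Degenerate regime ($k = d$).** Setting the neighborhood size equal
  to the embedding dimension forces $s_i = 1$: the multi-weight
  stabilization that defines MLLE vanishes and the fit is single-weight
  regularized LLE. Large neighborhoods compound this: on a 1000-point
  swiss roll, 100-NN balls bridge adjacent windings, the geodesic metric
  degenerates toward the Euclidean one, and the embedding does not
  unroll. The package runs in this regime (with a warning) because the
  full-dimension convention $d = D$ is part of the method's lineage, but
  users should keep $k$ comfortably above $d$ — or accept that the
  re-embedding is then a gentle spectral smoothing rather than manifold
  recovery. (A reference implementation fails outright here, producing
  undefined weights; this package degrades gracefully instead.)
* **Cosine dilution at large $d$.** Embedded coordinates are
  eigenvectors with equal norm per column; at $d$ close to $n$'s
  spectral bulk, trailing high-frequency modes contribute as much to a
  cosine as the leading smooth modes and wash out rank agreement.
  Moderate $d$ (or downstream whitening) avoids this.
* **Eigenvector mixing at very small $d$.** On high-aspect-ratio
  manifolds the second eigenvector can be a harmonic of the first
  latent direction rather than the second direction, so $d = 2$ is
  fragile; $d$ slightly above the intrinsic dimension is robust.
* **No incremental refitting.** New words are embedded through the
  out-of-sample extension; the training window itself is never updated.

## Problem sizes used by the examples and tests

All checks run on synthetic data generated in code: vocabularies of
60–1500 words, windows up to 1000, $D$ up to 100. These sizes were
chosen so that every stage (including the all-pairs geodesics and the
dense eigensolves) remains a desk-scale computation while still
exhibiting the phenomena of interest; the method itself is routinely
applied to windows of 1001–2001 words over vocabularies of hundreds of
thousands.
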