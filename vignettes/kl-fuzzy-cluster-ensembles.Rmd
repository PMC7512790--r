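---
title: "KL-divergence fuzzy cluster ensembles for noisy image segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{KL-divergence fuzzy cluster ensembles for noisy image segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(klfce)
```

## The problem

Segmenting a noisy grayscale image means partitioning its pixels into a small
number of intensity classes — tissue types in an MR slice, foreground and
background in a phantom. Fuzzy c-means (FCM) and its relatives return *soft*
partitions: each pixel gets a membership vector over the clusters, summing to
one. Different soft clusterers disagree, especially under noise, and no single
one dominates across images. A *cluster ensemble* runs several of them and
fuses the resulting membership matrices into one consensus partition that is
more stable than any member.

The fusion step is where the geometry matters. A pixel's concatenated
memberships form a discrete probability vector, and squared Euclidean distance
is a poor dissimilarity on the probability simplex. `klfce` therefore measures
the distance from a pixel's membership profile to a consensus cluster center
with the Kullback–Leibler divergence and minimises a fuzzy KL objective
directly.

## Model and algorithm

**Base partitions.** `generate_basic_partitions()` runs $r$ soft clusterers on
the same image. Each member $f$ returns an $n \times c_f$ row-stochastic
membership matrix $U_f$. The default ensemble has $r = 4$ members: two FCM
runs with independently derived seeds, and spatial FCM (SFCM) at $3\times 3$
and $5\times 5$ windows. FCM minimises
$J = \sum_k \sum_i u_{ik}^m \lVert x_k - v_i\rVert^2$ by alternating the
closed-form center and membership updates; SFCM additionally replaces each
membership by the average of itself and its neighbourhood mean,
$\hat u_{ik} = \tfrac12\big(\operatorname{mean}_{\omega \in NB(x_k)} u_{i\omega} + u_{ik}\big)$,
on every iteration.

**Concatenation.** `concatenate_normalize()` stacks the members column-wise
and divides by $r$, so each pixel becomes a probability vector
$y_k \in \Delta^{s-1}$ with $s = \sum_f c_f$.

**KL consensus (FCE_KL).** `fce_kl_fit()` minimises

$$J = \sum_{k=1}^{n} \sum_{i=1}^{c} u_{ik}^m \, D_{KL}(y_k \,\|\, o_i),
\qquad \sum_i u_{ik} = 1, \quad \sum_j o_{ij} = 1,$$

by alternating two closed-form stationarity updates obtained from the
Lagrangian: centers
$o_{ij} = \sum_k u_{ik}^m y_{kj} \big/ \sum_h \sum_k u_{ik}^m y_{kh}$
(a convex combination of profile rows, hence automatically on the simplex) and
memberships
$u_{ik} = 1 \big/ \sum_\ell \big(D_{KL}(y_k\|o_i) / D_{KL}(y_k\|o_\ell)\big)^{1/(m-1)}$.
The objective is recorded after each full update pair and is non-increasing;
iteration stops when $|J(t) - J(t-1)| < \varepsilon$ or at the iteration cap.

**Spatial variant (FCE_sKL).** `fce_skl_fit()` inserts the same neighbourhood
smoothing operator between the membership and center updates of every
iteration: memberships by the KL update, then
$\hat u = \tfrac12(u + \text{box mean of } u)$ over a $5\times 5$ window
(default), then centers and the objective from the smoothed $\hat u$, which
the fit also returns. Because the smoothing sits outside the stationarity
conditions, monotone descent of $J$ is not guaranteed for this variant and is
not asserted; termination is still by the $\varepsilon$/cap rule. At window 1
the variant reduces exactly to the plain fit.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `m` | 2 | Fuzzification coefficient (> 1). Controls overlap; $m \to 1$ approaches hard assignment. 2 is the standard choice and is used everywhere here. |
| `c` | phantom region count | Number of consensus clusters. Treated as prior knowledge; no model selection is attempted. |
| `window` | 3 (SFCM), 5 (FCE_sKL) | Odd side length, in pixels, of the square smoothing neighbourhood. Larger windows suppress more noise but blur thin structures. |
| `tol` | 1e-5 | Stop when successive objective values differ by less than this. |
| `max_iter` | 100 | Iteration cap. |
| `kl_floor` | 1e-12 | Floor on center entries inside $\log(p/q)$; membership matrices legitimately contain exact zeros. |
| `seed` | — | Controls initialisation; every pipeline is deterministic given its seed. |

## Numerical choices

* **Logarithm base.** Natural log. The base rescales $J$ and cancels in the
  membership ratio, so memberships are base-invariant; fixing it makes
  objective traces reproducible.
* **Zero handling.** $0 \log 0 = 0$ for profile entries; center entries are
  floored at `kl_floor` inside the ratio. A profile with zero divergence to
  one or more centers (within 1e-12) splits its mass equally among them — the
  singular limit of the update. The same convention handles a datum sitting
  exactly on an FCM center.
* **Initialisation.** FCM centers are `c` distinct data values sampled under
  the seed; consensus centers are `c` distinct profile rows. Both guarantee
  feasible (simplex) starting points and non-coincident centers.
* **Window borders.** The smoothing window is truncated to its intersection
  with the image and the centre pixel is always included, so the operator is
  an exact average everywhere and preserves row sums exactly.
* **Defuzzification ties.** Argmax with lowest-index wins — deterministic.
* **Degenerate inputs.** More clusters than distinct data values, constant
  images passed to the noise models, and empty consensus clusters all raise
  informative errors rather than producing NaNs.

## What the synthetic generators emulate

`make_two_value_phantom()` builds the classic 50×50 binary benchmark: two
vertical half-planes at intensities 0 and 1 with one straight compact
boundary. `make_trin_phantom()` builds a 64×64 four-region image as four equal
quadrants at equally spaced levels $\{0, \tfrac13, \tfrac23, 1\}$. The exact
pictorial content of the originals these imitate is not specified anywhere in
text, so both layouts are deliberate stand-ins chosen for determinism and
compact boundaries; conclusions that depend on boundary *shape* (not length or
compactness) do not transfer.

A noise level of $r\%$ means a standard deviation of $r/100$ times the clean
image's intensity range — the common convention in the spatial-FCM
literature, and the one that makes 50% noise on a 0/1 image mean
$\sigma = 0.5$. `add_gaussian_noise()` adds i.i.d. $N(0, \sigma^2)$ without
clipping; `add_rician_noise()` applies the magnitude-MRI model
$\sqrt{(I+e_1)^2 + e_2^2}$, which is Rayleigh where the clean signal is zero.
What these phantoms do **not** emulate: anatomical structure, partial-volume
effects, intensity inhomogeneity fields, and spatially correlated noise. A
perfect score here shows noise robustness on piecewise-constant images, not
clinical performance.

## Design choices where the design was open

* **Ensemble composition.** The four default members are fully specified by
  the FCM/SFCM updates above; diversity comes from initialisation and spatial
  scale rather than from algorithm families whose internals (nonlocal-means
  weighting, possibilistic variants) are not reproducible from their names
  alone. The composition is configurable per member, including per-member
  cluster counts.
* **Objective for the spatial variant.** $J$ is evaluated with the *smoothed*
  memberships, matching the step order membership → smoothing → centers →
  objective; the smoothed memberships are what the fit returns.
* **Smoothing on the first iteration.** The step order above is applied
  literally from iteration 1; no warm-up without smoothing.
* **Label alignment.** Cluster indices are arbitrary, so before accuracy is
  computed the predicted labels are relabeled by the agreement-maximising
  permutation, found exhaustively (exact for the ≤ 8 classes supported; all
  experiments here use ≤ 4). The empty-vs-empty class Jaccard is defined as 1.
* **Replicates.** The experiment driver defaults to 5 replicates per noise
  cell with mean ± sd reporting, since single noisy draws of a stochastic
  benchmark are not interpretable; per-cell seeds derive from one master seed
  and are recorded in the output table.

## Problem sizes and verification

The test suite verifies the iterative fits against independent numeric
oracles: brute-force minimisation of the FCM objective over the membership
simplex (logistic parameterisation, multi-start BFGS) on instances with
$n \le 5$, and of the KL consensus objective over memberships *and* softmax-
parameterised centers on instances with $n \le 5$, $s \le 4$, $c = 2$. The
benchmark grids use the 50×50 two-value phantom (5 replicates per cell) and
the 64×64 quadrant phantom (3 replicates per cell) at noise levels from 5% to
50% — sizes at which a full member-plus-consensus pipeline runs in under a
second, so the whole suite completes in a few minutes.

## Known limitations

* Single-pass membership smoothing cannot correct a pixel whose neighbourhood
  offers no majority — in particular boundary pixels whose noise crosses the
  class midpoint. At heavy noise (50% Gaussian) the spatial ensemble therefore
  plateaus near SA ≈ 0.90–0.91 on the two-value phantom while still
  dominating every individual member; members carrying nonlocal (patch-based)
  information would be needed to push further.
* Grayscale only ($d = 1$); no color features, no volumetric grids.
* The number of clusters is prior knowledge; no selection criterion is
  provided.
* All members run on the same image; weighting members by estimated
  reliability is out of scope.
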