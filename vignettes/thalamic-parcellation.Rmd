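---
title: "Thalamic nuclei parcellation from diffusion ODFs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thalamic nuclei parcellation from diffusion ODFs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thalparc)
```

## The problem

The thalamus relays nearly all ascending signals to the cortex through a
mosaic of cytoarchitectonically distinct nuclei, yet conventional MRI
contrast is almost uniform across them. Because each nuclear group carries
fiber populations with characteristic orientations, the angular profile of
water diffusion — the orientation distribution function (ODF) — separates
them where scalar contrasts cannot. `thalparc` segments the thalamus into
`k = 7` groups of nuclei by clustering voxels on two equally weighted
features: their spatial position and the full spherical-harmonic (SH)
representation of their diffusion ODF. Using the complete ODF rather than a
summary statistic (such as the principal tensor eigenvector) is the point:
crossing fiber populations inside the thalamus are invisible to the tensor
but visible to the ODF.

## ODF reconstruction

For each voxel, the single-shell diffusion signal $S(\mathbf{u})$ with
unweighted reference $S(0)$ is transformed to the double-log domain and
expanded in the real symmetric SH basis of maximum order $\ell = 6$:

$$
\ln\!\left(-\ln \frac{S(\mathbf{u})}{S(0)}\right)
  = \sum_{j=1}^{R} c_j\, Y_j(\mathbf{u}),
\qquad R = \frac{(\ell+1)(\ell+2)}{2} = 28 .
$$

The basis (`sh_basis()`) orders coefficients by $\ell$ ascending, $m$
ascending; only even orders appear because diffusion is antipodally
symmetric. The constant-solid-angle (CSA) q-ball estimator then maps these
coefficients to the ODF analytically:

$$
\mathrm{ODF}(\mathbf{u}) \;=\; \frac{1}{4\pi} \;+\;
\frac{1}{16\pi^2}\,
\mathrm{FRT}\!\left\{\Delta_b\, \ln\!\left(-\ln\tfrac{S}{S(0)}\right)\right\}
(\mathbf{u}),
$$

where both the Laplace–Beltrami operator $\Delta_b$ (eigenvalue
$-\ell(\ell+1)$) and the Funk–Radon transform (eigenvalue $2\pi
P_\ell(0)$) are diagonal in the SH basis, so the whole transform is one
multiplier per order (`csa_transform()`). The constant coefficient is
fixed at $1/(2\sqrt{\pi})$ so every ODF integrates to exactly 1 over the
sphere. The transform is verified in the test suite against a great-circle
quadrature implementation of the Funk–Radon transform.

Per-voxel uncertainty is handled by residual bootstrapping
(`bootstrap_mean_odf()`): the SH fit is computed once, its per-direction
residuals in the double-log domain are resampled with replacement, the fit
and CSA transform are repeated 50 times, and the coefficient-wise mean is
the clustering input. Because the CSA transform is linear, averaging
post-transform ODF coefficients and averaging pre-transform fit
coefficients are the same operation; we average post-transform for
transparency.

### Numerical choices

* **Clipping.** The estimator requires $0 < S/S(0) < 1$; the ratio is
  clipped to $[\delta, 1-\delta]$ with $\delta = 10^{-3}$ before the
  double log. Noise occasionally pushes $S$ above $S(0)$; clipping keeps
  the fit finite without discarding directions.
* **Regularization.** The least-squares fit uses Laplace–Beltrami ridge
  regularization with weight $\lambda = 0.006$ on $(\ell(\ell+1))^2$, the
  standard setting for order-6 fits on 64 directions. $\lambda = 0$ is
  allowed whenever the system is overdetermined; with fewer directions
  than coefficients and $\lambda = 0$ the fit refuses to run.
* **Smoothing.** Pre-smoothing uses a separable sampled Gaussian with
  $\sigma = 0.8$ mm per axis (converted to voxel units per axis, reflect
  padding, which conserves mass for interior-supported images). Note that
  at $\sigma$ well below the voxel size a sampled kernel is close to a
  delta, so the smoothing is gentle by construction; its mm-domain
  isotropy is only measurable for $\sigma$ at or above the voxel size.

## Mask refinement

The thalamus mask (produced upstream by anatomical segmentation; consumed
here as input) is refined in a single pass (`refine_mask()`):

* voxels with CSF probability $\ge 0.05$ are removed (partial-volume
  contamination by cerebrospinal fluid), and
* voxels within 2 mm of the mask border (boundary-inclusive, measured by
  an exact anisotropic Euclidean distance transform from in-mask voxel
  centers to the nearest background voxel center) with FA $> 0.55$ are
  removed (partial-volume contamination by the internal capsule).

Both rules are evaluated against the *input* mask's border. The operation
is idempotent whenever the retained tissue keeps FA below the threshold
near the newly exposed border — true in the thalamus proper, where FA is
around 0.3. If high-FA tissue remains adjacent to the new border a second
pass would erode further; this is a property of any border-relative rule
and the reason refinement is defined as a single pass.

## Clustering

Each in-mask voxel contributes a feature row
$[\,x, y, z,\; S_{\mathrm{ODF}}\, c_1, \dots, S_{\mathrm{ODF}}\, c_{28}\,]$
with positions in mm (so anisotropic voxels are honored) and
$S_{\mathrm{ODF}} = 55$, the published scaling that places ODF distances
inside the range of the spatial distances. The decision metric is

$$
d^2(v, C) \;=\; \alpha\, d^2_{\mathrm{pos}}(v, C)
  \;+\; (1-\alpha)\, d^2_{\mathrm{ODF}}(v, C),
\qquad \alpha = \tfrac12,
$$

with both terms Euclidean. Squared mixing makes this exactly plain
k-means on the concatenated weighted feature vector
$[\sqrt{\alpha}\,\mathbf{p},\; \sqrt{1-\alpha}\, S_{\mathrm{ODF}}\,
\mathbf{c}]$, so the per-block mean is the exact Lloyd centroid update and
the objective is provably non-increasing (asserted on every run). An
unsquared mixing variant is exposed via
`cluster_config(distance_mix = "linear")` for comparison; squared is the
default because it is the form with exact centroid updates.

**Initialization** is data-driven (`init_centroids()`): many (default
5000) randomly initialized position-only k-means runs are computed, every
run's centroids are matched one-to-one (Hungarian assignment) to those of
the *lowest-objective* run, and the aligned centroids are averaged
slot-wise. Averaging against the best run, rather than against whichever
run happened to come first, is a deliberate design choice: with an
arbitrary reference the average inherits the reference's solution mode,
and when that reference is a poor local optimum the averaged start can
pull the final clustering into a worse basin. The best run is mode-stable
across seeds, which makes the averaged initialization — and hence the
whole pipeline — insensitive to the random seed. The ODF slot of each
initial centroid is filled with the mean scaled ODF vector over the
26-neighborhood of the voxel containing the averaged position.

The averaged initialization should be read as a robust starting point,
not an estimator of cluster centers: individual random-start runs land in
assorted local optima and their average carries a bias of a few
millimetres on idealized blob data. What matters — and what the tests
assert — is that it covers every true cluster bijectively and that
k-means started from it recovers the exact partition.

**Degeneracies.** An empty cluster during iteration is re-seeded at the
voxel farthest from its assigned centroid (logged). Final labels are
renumbered deterministically by descending cluster size, ties broken by
lexicographic centroid order, so that repeated runs are bit-identical and
voxel order is irrelevant.

## The angular-difference baseline

The strongest previously published local feature is the angular
difference (AD) between principal tensor eigenvectors. `kmeans_ad()`
replaces the ODF distance with
$(s_{\mathrm{AD}} \cdot \mathrm{AD}(\mathbf{e}_1^v,
\mathbf{d}_C))^2$ where $\mathrm{AD}(\mathbf{u},\mathbf{v}) =
\arccos|\mathbf{u}\cdot\mathbf{v}| \in [0, \pi/2]$ (diffusion directions
are axes, so sign is meaningless) and $s_{\mathrm{AD}} = 6$, the
published scaling that brings the AD term (max $\approx 9.4$) into the
range of mm-scale spatial distances. The cluster direction is updated as
the principal eigenvector of the mean dyadic tensor
$\frac{1}{n}\sum \mathbf{v}\mathbf{v}^\top$ of the member vectors — the
sign-invariant mean ($\{+\mathbf{v}, -\mathbf{v}\}$ averages to
$\pm\mathbf{v}$, where the arithmetic mean would collapse to zero).

## Evaluation

`cluster_metrics()` matches the clusters of two labelings by maximum
voxel overlap (Hungarian assignment on the contingency table, verified
against exhaustive permutation search for small $k$) and reports, per
matched pair: Dice overlap $2|A \cap B| / (|A| + |B|)$, Euclidean
centroid distance in mm, and the modified (Dubuisson–Jain) Hausdorff
distance between cluster contours — the larger of the two directed mean
nearest-neighbour distances, computed on 6-connectivity boundary voxels
mapped to mm. Consensus across subjects uses majority voting with ties
broken to the lowest label (tie counts reported). Hemispheric symmetry of
per-cluster normalized volumes or centroid border distances is tested
with a two-sided Wilcoxon signed-rank test using Pratt zero handling
(zeros are ranked, then discarded from the statistic; normal
approximation with zero and tie corrections) — implemented in-package
because the base R test drops zeros entirely, and cross-checked against
`stats::wilcox.test` in the no-zero regime.

## The synthetic phantom

Real thalamic MRI cannot ship with the package, so every claim is
exercised on a multi-tensor phantom (`generate_phantom()`) built to have
exactly the structure the method assumes:

* **Geometry.** An ellipsoid of semi-axes $22 \times 17 \times 11$ mm on
  a $24 \times 24 \times 18$ grid of $2 \times 2 \times 2.5$ mm voxels
  (about 1700 in-mask voxels — computed in seconds). The flattened shape
  mirrors thalamic proportions and keeps the seven angular-sector
  regions spatially compact; in a rounder volume, full-depth wedges stop
  being compact along the axis and no position-aware method should be
  expected to recover them.
* **Fiber model.** Each region carries a distinct *pair* of crossing
  fibers (volume fractions 0.6/0.4) drawn from 14 quasi-uniform
  hemisphere directions, with per-fiber eigenvalues
  $(1.7, 0.3, 0.3)\times 10^{-3}$ mm$^2$/s — the canonical simulation
  values for a coherent fiber population. Crossing populations keep the
  tensor-fit FA at thalamus-like values (roughly 0.45–0.55) while the
  ODFs remain strongly orientation-distinct; this is exactly the regime
  in which the full ODF outperforms the tensor summary, and it is why
  the AD baseline trails the ODF pipeline on this phantom as it does in
  vivo.
* **Signal and noise.** $S(\mathbf{u}) = S_0 \sum_i f_i \exp(-b\,
  \mathbf{u}^\top D_i \mathbf{u})$ across 64 hemisphere directions at
  $b = 1000$ s/mm$^2$ plus one $b = 0$ volume, with Rician noise
  (magnitude of two independent Gaussian channels of std $S_0 /
  \mathrm{SNR}$, default SNR 30 referenced to $S_0$) because magnitude
  MR data is Rician.
* **Contamination rims.** A CSF-like rim (isotropic diffusivity
  $3\times10^{-3}$ mm$^2$/s, CSF probability 0.9) lines the inferior
  border and a highly anisotropic internal-capsule-like shell (per-fiber
  eigenvalues $(1.9, 0.2, 0.2)\times10^{-3}$, FA $\approx 0.85$) lines
  the superior border, each 2 mm thick, so the refinement rules have
  real targets.

`simulate_scan_rescan()` reuses one noiseless phantom with two
independent noise draws — the synthetic analog of two same-day
acquisitions of one subject.

**What the phantom does not emulate:** real nuclear geometry (atlas
shapes), spatially varying SNR, motion and eddy-current artifacts,
susceptibility distortion, and partial-volume mixing at region borders.
Passing tests therefore demonstrate the correctness and internal
reproducibility of the machinery under the model's own assumptions, not
clinical performance.

## Problem sizes and determinism

The test suite and the acceptance script run the full pipeline on the
default phantom with the initialization scaled to 200 runs (from the
production default of 5000) — enough for the averaged start to stabilize
at this problem size, as the seed sweeps in the test suite show. The
bootstrap stays at its production value of 50 replicates. All randomness
(noise, bootstrap, initialization) is seeded, and identical seeds give
bit-identical label volumes; the seeds used by the tests are fixed
arbitrary integers.

## Known limitations

* `k = 7` is a fixed input, not estimated from data.
* $S_{\mathrm{ODF}} = 55$ and $s_{\mathrm{AD}} = 6$ are published
  empirical constants; no per-dataset re-estimation is attempted.
* Refinement is a single pass and deliberately not iterated (see above).
* No registration of any kind is provided; multi-subject operations
  (majority voting) assume pre-aligned inputs, which the phantom suite
  provides natively.
* Single-shell acquisitions only; multi-shell models and ODF peak
  extraction are out of scope.
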