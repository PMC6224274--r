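---
title: "Outline morphometrics of barnacle nauplius larvae: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Outline morphometrics of barnacle nauplius larvae: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(naupliomorph)
```

## The problem

Barnacle (Cirripedia) nauplius larvae carry a pear-shaped cephalic shield
with a unique pair of anterolateral frontal horns and a posterior dorsal
thoracic spine. The shield outline is a natural target for landmark-free
("outline") geometric morphometrics: homologous landmarks are scarce, but
the closed boundary is well defined across species. This package implements
a full comparative workflow around that idea:

1. quantify each outline with **normalized elliptic Fourier analysis**
   (EFA);
2. build a **morphospace** by PCA of the Fourier coefficients, and
   visualize axes as hypothetical reconstructed outlines and
   thin-plate-spline deformation grids;
3. test how shape relates to **size (allometry)** and **trophic mode**
   (feeding planktotrophic vs non-feeding lecithotrophic larvae) with
   multivariate regression, shape scores, sequential MANCOVA with
   permutation tests, vector correlations, and balanced bootstraps;
4. measure **phylogenetic signal** (Blomberg's K, its multivariate
   generalization K~mult~) and account for phylogeny in the regression
   models under a Brownian-motion model.

Because the original outline collections of this literature were digitized
by hand from published drawings and are generally not redistributable, the
package also ships a **synthetic nauplius generator** with exact analytic
ground truth, so every stage of the pipeline is testable end to end.

## Coordinate and orientation conventions

Outlines live in a plane with x rightward and y upward; the larval anterior
points to **+y** and the tail spine to −y, so the standardized sampling
start — "the most posterior point" — is well defined (ties broken by
minimal x). Ingested outlines are forced counterclockwise (positive signed
area). Image masks are row-inverted on reading so the same frame applies.

Reflection is deliberately **not** normalized away: all outlines share one
chirality after counterclockwise ingestion, and mirroring (dorsal vs
ventral view) is biologically meaningful, so collapsing it silently would
be wrong. Mixed-view datasets must be reflected explicitly by the user.

## Elliptic Fourier analysis

For a closed outline sampled as points $(x_i, y_i)$, the coordinates are
treated as periodic functions of the cumulative chord length $t \in [0, T]$
($T$ = perimeter). Each harmonic $n$ contributes four coefficients
$(a_n, b_n)$ for $x(t)$ and $(c_n, d_n)$ for $y(t)$:

$$x(t) = a_0 + \sum_{n\ge 1} a_n \cos\tfrac{2\pi n t}{T} + b_n \sin\tfrac{2\pi n t}{T},$$

and likewise $y(t)$. Two decomposition variants are provided:

* `method = "integral"` (default): the classical closed-form Fourier
  integrals of the piecewise-linear curve. This is the formulation used
  throughout the pipeline; it is robust to unevenly spaced vertices. Its
  truncation error at the Nyquist limit is $O(1/K)$ for a $K$-gon, because
  the coefficients belong to the piecewise-linear interpolant, not to the
  vertex sequence.
* `method = "dft"`: the discrete Fourier transform of the vertices under
  index parameterization. With $N = \lfloor K/2 \rfloor$ harmonics the
  truncated series is the trigonometric interpolant and reproduces every
  vertex to machine precision — the right tool for verifying that the
  coefficient pipeline is lossless. After uniform arc-length resampling
  (the standard first step, default 200 points) the two parameterizations
  coincide.

**Normalization** removes translation (centroid terms zeroed), starting
point, rotation and scale using the first-harmonic ellipse: the phase is
rotated so the series starts at the semi-major axis, the plane is rotated
so that axis lies along x, and all coefficients are divided by the
semi-major axis length. The result always has $a_1 = 1$, $b_1 = c_1 = 0$;
these three constants are dropped from the downstream **shape vector**
(harmonics 1..15 by default, $4 \times 15 - 3 = 57$ variables). Note the
consequence for orientation: after normalization the *long* axis of the
shape lies along x, so an elongated nauplius appears "lying down" in the
normalized frame.

The 180° ambiguity of the semi-major axis is resolved deterministically by
requiring the mean of the first quarter of reconstructed points to have
positive y, falling back to the sign of $d_1$ for shapes symmetric enough
to leave that functional at zero. With this rule, normalized coefficients
of an arc-uniform outline are invariant to similarity transforms and start
shifts to ~1e−12; the package's tests assert 1e−8 over 1000 random
transforms.

**Harmonic count**: per outline, harmonic power is
$(a_n^2+b_n^2+c_n^2+d_n^2)/2$; `choose_n_harmonics()` returns the smallest
N whose cumulative power fraction exceeds 99% (configurable) for *every*
outline in the set. A pure ellipse needs N = 1. The default of 15
harmonics is kept as a fixed, comparable feature length across analyses.

## Morphospace

PCA is computed on the variance–covariance matrix of the shape vectors
(divisor $n-1$, covariance not correlation — the coefficients share a
scale). Axis signs are fixed (largest-magnitude loading positive) so plots
and vector correlations are reproducible; the direction of a PC axis is
otherwise arbitrary. Hypothetical outlines along an axis are rebuilt from
$\bar{v} + s\,e_k$ at $s = \pm 2\,\mathrm{SD}$ of the observed scores: the
mean vector **is added** — a pure multiple of an eigenvector is not a valid
normalized coefficient set and cannot yield a nauplius-like outline, so
reconstruction is always relative to the mean shape.

Shape change is visualized with thin-plate-spline deformation grids
(kernel $U(r) = r^2 \log r$, affine + bending terms, exact interpolation at
the control points), mapping the mean outline onto a target with
index correspondence. Bending energy is zero exactly for affine maps.
The default grid is 24 × 24 nodes with a 10% bounding-box margin.

## Allometry and trophic-mode statistics

* `mv_regress()` fits each shape variable on the design by least squares;
  the fit's $R^2$ pools sums of squares across all 57 columns.
* `shape_score()` implements the one-dimensional regression summary
  $s = y\,\beta^T (\beta\beta^T)^{-1/2}$ — the projection of each species'
  shape onto the regression vector, exact (correlation 1 with the
  covariate) when the data are noise-free.
* `mancova()` computes sequential (Type I) sums of squares by nested model
  comparison. Significance uses **residual randomization (RRPP)**: for
  each term, residuals of the reduced model are row-permuted and added
  back to its fitted values, and the F ratio is recomputed;
  $p = (\#\{F^* \ge F\}+1)/(n_{perm}+1)$, so p can never be 0 and all
  permutation output is exactly reproducible given a seed. The effect size
  is $Z = (F - \bar{F^*})/\mathrm{sd}(F^*)$ on the raw F scale (reference
  implementations vary in the transform they apply; the raw scale is
  documented here as this package's convention). The default 999
  permutations is a convention, not an inherited setting.
* `vector_correlation()` is $R = |v_1 \cdot v_2| / (\|v_1\| \|v_2\|)$ with
  $\theta = \arccos R$ in degrees; the absolute value reflects the
  arbitrary PC direction. The permutation test permutes **covariate
  values** across species by default (permuting shape rows is available as
  an option); which of the two the original analyses used is not
  documented anywhere we could find, so the choice is explicit and
  seedable here.
* `allometry_free()` returns residuals of shape on size (plus the mean
  shape for reconstruction), and projects them onto the *original*
  morphospace eigenvectors, so adjusted and unadjusted species can be
  drawn in one ordination.
* `bootstrap_groups()` is a balanced case-resampling bootstrap: each of
  the (default 1000) replicates draws the same number of species — the
  size of the smaller group — with replacement from each trophic mode,
  correcting for unequal group membership.

## Phylogenetic comparative methods

The Brownian covariance $C_{ij}$ is the shared root-to-MRCA path length
(trees need not be ultrametric; path lengths are used as given). Blomberg's
K compares the observed ratio of the mean squared error about the GLS
phylogenetic mean to the phylogenetically corrected MSE against its
Brownian expectation $[\mathrm{tr}(C) - n/\mathbf{1}^TC^{-1}\mathbf{1}]/(n-1)$;
K = 1 matches Brownian motion exactly, and on a star tree with equal
branches K is identically 1. K~mult~ generalizes the ratio to multivariate
data by transforming centered rows with $C^{-1/2}$ (symmetric
eigendecomposition, eigenvalues floored at 1e−12 for near-ultrametric
stability); with one trait it reduces to K exactly. Significance permutes
tip rows.

Ancestral states are the maximum-likelihood (equivalently GLS) estimates
under Brownian motion: the internal-node values minimizing
$\sum_{\text{branches}} (\Delta)^2 / v$, solved as a sparse weighted
tree-Laplacian system with tips as boundary values. Zero-length branches
are replaced by a small epsilon (1e−8 of tree height) with a warning.
These estimates place internal nodes in the morphospace
(`phylomorphospace_coords()`).

`phylo_lm()` premultiplies the response *and* the full design matrix
(including its intercept column) by $C^{-1/2}$ and reruns the sequential
MANCOVA machinery on the transformed data; on a star tree with unit
branches it reduces exactly to `mancova()`. Simulations in the test suite
show the whitened test holds its nominal type-I error on
Brownian-correlated null data where the ordinary test is anticonservative.

A note on rootedness: a `phylo` object is read as rooted at its basal
node. The one shape treated as unrooted is a basal trichotomy on an
otherwise binary tree (the conventional encoding of an unrooted binary
tree), which is rejected; genuine polytomies, including star trees, are
accepted, since their Brownian covariance equals that of any zero-length
resolution.

## The synthetic generator: what it emulates and what it does not

`make_nauplius_outline()` is a star-convex polar model: an ellipse with
the requested width/length ratio, two symmetric anterior Gaussian bumps
(frontal horns, at ±50° from the anterior axis, angular SD 0.15 rad by
default) and one posterior bump (tail spine). This model was chosen over,
say, boolean unions of primitives because it guarantees simple closed
curves and analytic ground truth: after an anisotropic rescale that pins
the bounding box, the generated polygon's length and width are *exact*,
and a short fixed-point calibration drives the tip-to-base horn length to
the requested value (relative error < 1e−9 when feasible). Horn lengths up
to 0.6 of larval length are realizable for any aspect ratio in
\[0.3, 1.5\] and tail fraction up to 0.3; beyond that the horns themselves
start to dominate the bounding box, the relative horn length saturates,
and the generator refuses with an informative error rather than silently
delivering a shorter horn.

`simulate_species_set()` draws a 102-species community by default:
log-normal sizes (meanlog = log 350 µm, sdlog = 0.55), aspect ratio
$0.72 + 0.18(\log \text{size} - \log 350) + N(0, 0.045)$, a Bernoulli(0.3)
lecithotrophic fraction, and relative horn length
$0.18 + 0.12\,[\text{planktotrophic}] + N(0, 0.045)$. These conditions
were chosen once to emulate the empirical structure of the barnacle
nauplius system: a dominant size/aspect-ratio axis (PC1, vector
correlation with the size-regression vector ≈ 0.95–1.0 across seeds), a
second axis carried by relative horn length separating trophic modes
(typically R ≈ 0.94–1.0, though occasional 102-species draws mix this
axis — real sampling variability, not a bug), a multivariate size $R^2$
around 0.4, and a scalar aspect-ratio-on-log-size $R^2$ around 0.7–0.8.

What the generator does **not** emulate — and hence what green tests do
not certify about real data: digitization and spline-smoothing noise of
hand-traced drawings, left–right asymmetry, appendage remnants, the
"Pinocchio effect" of extremely long tail processes on Fourier fits,
measurement error in manually landmarked horn tips, and any phylogenetic
structure in the trait values (trees and Brownian traits are simulated
separately by `simulate_tree_bm()`; the species table's traits are i.i.d.
given size and trophic mode).

## Numerical choices and degenerate inputs

* Uniform arc-length resampling (default 200 points) starts at the most
  posterior point; ties break toward minimal x. Resampling is idempotent
  on outlines whose chords are already uniform.
* Mask tracing smooths the binary mask with a Gaussian (σ = 1.5 px,
  configurable) before extracting the sub-pixel 0.5-level contour; the raw
  marching-squares contour of a binary image overestimates perimeters by
  ~5%, the smoothed one by < 0.2% on a rasterized disk. Masks must contain
  exactly one component not touching the border.
* Eigenvalues of shape covariance matrices are clamped at 0; eigenvector
  signs are fixed by the largest loading.
* Degenerate inputs error early with the offending field named: zero
  perimeter outlines, constant shape matrices, rank-deficient designs,
  empty factor levels, zero vectors in correlations, degenerate first
  harmonics, collinear TPS control points, duplicate tip labels, missing
  tips.
* All randomness flows through one explicit seed argument per call; the
  caller's RNG state is saved and restored, so library calls never leak
  global state. Permutation p-values use the +1/+1 convention.

## Problem sizes used by the test suite

The packaged checks run at deliberately modest scale, chosen as the
smallest sizes at which the relevant asymptotics are already visible:
type-I error of the MANCOVA terms over 500 null datasets (n = 30, 199
permutations each); Brownian calibration of K over 200 simulated 64-tip
Yule trees and of K~mult~ over 100 trees with 57 traits; bootstrap
coverage over 200 simulated 100-species communities with 1000 replicates
each; 1000 random similarity transforms for the normalization invariance.

## Known limitations

* The EFA normalization assumes a non-degenerate first-harmonic ellipse;
  shapes whose first harmonic collapses (space-filling or retrograde
  outlines) are rejected rather than normalized.
* `measure_linear()` needs horn tip *and* base landmarks to produce horn
  lengths — the outline alone does not determine where a horn "starts",
  which is also why the original analyses measured horn length manually.
* The MANCOVA is sequential (Type I): term order matters and is part of
  the scientific question (size first, then trophic mode, then their
  interaction).
* K and K~mult~ inherit the usual caveats of permutation tests on small
  trees; below ~10 tips the permutation null is coarse.
* The TPS solver is dense; grids over a few thousand control points will
  be slow. Outlines at the default 200 points are instantaneous.
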