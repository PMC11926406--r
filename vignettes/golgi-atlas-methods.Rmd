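---
title: "Methods: quantitative sub-Golgi colocalization and the enzyme atlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative sub-Golgi colocalization and the enzyme atlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(golgiatlas)
```

## The measurement problem

Golgi-resident glycosyltransferases are not distributed uniformly across the
stack: each enzyme occupies a characteristic band along the cis-to-trans
axis, and the differences between enzymes can be smaller than the axial
extent of a single cisterna. Dual-label 3D confocal imaging turns that
question into a statistical one: given two co-registered voxel channels of
the same Golgi ribbon, how similar are the two enzymes' spatial
distributions, and can a whole panel of pairwise similarities be summarized
as a low-dimensional "atlas" in which position reflects sub-Golgi
localization?

This package implements that measurement chain end to end:

1. **Costes automatic thresholding + voxel Pearson correlation** — the
   per-cell colocalization statistic.
2. **Otsu / maximum-entropy segmentation + nMDP colormaps** — a per-voxel
   view with the `Icorr` / `Inega-corr` summary fractions.
3. **Group statistics** — mean ± SEM per pair, Dunnett many-to-one
   comparisons against a control pair, unpaired t-tests.
4. **The atlas** — mean correlations to dissimilarities `d = 1 - r`,
   metric SMACOF MDS into 3D, then PCA to two display axes.
5. **A seeded synthetic-scene generator** with known ground truth, used to
   validate every step above.

## Colocalization statistics

### Costes thresholding

The Pearson correlation of two raw channels is dominated by the
background/foreground contrast, so a threshold is needed — and choosing it
by hand biases the result. The Costes procedure removes that choice: fit
the orthogonal (total-least-squares) regression `B = slope * A + intercept`
to the voxel scatter, then walk candidate thresholds `t_a` down from
`max(A)` with `t_b` tied to the regression line, and at each step compute
the correlation of the *below*-threshold voxel set. The accepted threshold
is the largest `t_a` at which the below set is uncorrelated (`r <= 0`):
everything above is signal that cannot be explained as background.

Choices a faithful implementation must pin down, and what this package
does:

* **Regression flavor** — orthogonal regression via the principal axis of
  the 2x2 channel covariance, because both channels carry noise; ordinary
  least squares of B on A would flatten the slope. Channels with a
  non-positive principal-axis slope are rejected (`negative-slope` error):
  the procedure is undefined for anti-correlated channels.
* **Below-set logic** — "A below *and* B below" by default, the common
  published reading; the union variant is exposed
  (`below_set = "or"`) for sensitivity checks.
* **Scan granularity** — candidates are the occupied intensity levels of
  channel A only. This is finite, deterministic and
  resolution-independent; the scan is evaluated for *all* candidates in
  one `O(n log n)` sweep (voxels enter the below set in order of a
  per-voxel entry level), so the full threshold-vs-correlation curve is
  returned for auditing (`$scan`).
* **Degenerate stops** — a candidate only counts if the below set has at
  least two voxels and at least two distinct values in each channel.
  If no zero crossing exists the thresholds fall to the channel-A minimum
  (with `t_b` still on the regression line, keeping the reported pair
  self-consistent) and `converged = FALSE` is recorded.

The per-cell statistic is then the Pearson correlation over the *signal*
set. The default signal set is the union `A > t_a OR B > t_b`
(`voxel_policy = "or"`): mutually exclusive staining then enters the
correlation and correctly penalizes non-colocalized pairs. The
intersection policy is available and recorded in provenance, since
commercial implementations do not document their choice.

### nMDP and Icorr

The normalized mean deviation product gives a per-voxel view. Each channel
is first segmented (Otsu or Kapur maximum-entropy threshold, foreground
strictly above threshold), and statistics are computed over the *union* of
the two foregrounds — segmenting first matters, because background voxels
would otherwise pull the channel means down and inflate apparent
correlation. Over the foreground, with means `abar`, `bbar` and maxima
`amax`, `bmax`:

```
nMDP(x) = (A(x) - abar) (B(x) - bbar) / ((amax - abar) (bmax - bbar))
```

`Icorr` is the fraction of foreground voxels with positive nMDP, and
`Inega_corr = 1 - Icorr` holds exactly by construction. The rendered
colormap clamps values to `[-1, 1]`; the raw field is kept unclamped
because values below -1 are mathematically possible (a voxel far below
one mean and far above the other), and clamping silently would bias any
downstream statistic of the field.

Both threshold rules are implemented as exhaustive criterion
maximizations over the histogram levels with a deterministic tie-break
(lowest optimal threshold), and the test suite holds them to *exact*
agreement with brute-force scans. Integer-valued images are binned at one
bin per integer level so thresholds are actual intensity levels; float
images use 256 equal-width bins by default.

## Group statistics

Per-pair summaries are mean, sample SD (n - 1) and SEM over cells. The
many-to-one comparisons use classic equal-variance Dunnett: pooled
within-group variance, t statistics for each treatment-vs-control
contrast, and a family-wise adjusted p from the joint multivariate t
distribution of the contrasts (correlation
`rho_ij = sqrt(n_i n_j / ((n_i + n0)(n_j + n0)))`, df = N - k). The
multivariate t probability is evaluated by numerical integration
(mvtnorm, absolute tolerance 5e-4, so adjusted p-values carry about
±0.002); the reported adjusted p is floored at the unadjusted two-sample
p, since the family-wise probability can never be smaller than the
marginal one and integration noise should not suggest otherwise. The
equal-variance form is the canonical test named in figure legends;
a Welch-type variant is out of scope. Stars follow the usual
0.05 / 0.01 / 0.001 / 0.0001 ladder.

## The atlas

Mean correlations per unordered pair (directional means averaged if both
orders were measured) become dissimilarities `d = 1 - r`. Two readings of
"normalized" correlation are supported and recorded in provenance:

* `normalization = "none"` (default): `d = 1 - rbar` directly.
* `normalization = "self-control"`: each pair mean is divided by the
  geometric mean of the two dual-label self-pair means and capped at 1,
  treating the same-enzyme two-fluorophore control as the attainable
  ceiling before applying `d = 1 - r`.

The default is "none" because the normalization actually used upstream of
published atlases is not documented; emitting both keeps results
auditable. Note `d = 1 - r` lies in `[0, 2]` but is *not* a metric — the
triangle inequality is not assumed anywhere.

Embedding is metric SMACOF: iterative stress majorization of the raw
stress `sum_{i<j} (delta_ij - d_ij(X))^2` in 3 dimensions, with 8
seeded random restarts keeping the lowest-stress solution. Restarts are
used instead of a single fixed random start because stress majorization
only guarantees a local optimum, and a fresh implementation cannot
reproduce any particular upstream RNG stream; with restarts the geometry
is stable across seeds. Iteration stops when an update improves stress by
less than 1e-12 (or at 3000 iterations) — tight enough that labels with
zero dissimilarity coincide to well below 1e-6. Stress is non-increasing
across iterations by construction, and the per-iteration trace is
returned.

The 3D configuration is projected to display coordinates by PCA
(covariance eigen-decomposition, top two components). MDS solutions are
defined only up to rigid motion, so the projection fixes a deterministic
sign convention (largest-magnitude loading positive per component);
comparisons in the test suite are made modulo that convention, and rank
statistics (Spearman) are used where only the ordering is meaningful.

## The synthetic generator

The generator renders what the analysis consumes: two-channel 3D volumes
of one cell in which both channels share the cell's geometry and differ
only in their axial placement and their noise.

* **Geometry** — the ribbon is a chain of `n_ministacks` (default 10)
  Gaussian ministacks placed at equal arclength along a gentle arc through
  the axial mid-plane (configurable control polyline). Each ministack has
  a local cis-to-trans axis tilted away from z by up to
  `axis_jitter_deg` (default 10°) at a random azimuth. A ribbon-of-stacks
  rather than a continuous sheet creates the shared lateral structure real
  dual-label images have.
* **Enzyme profile** — a Gaussian along the local axis at `axial_mu`
  (um from the ministack center) with spread `axial_sigma`
  (default 0.25 um, roughly one to two cisternae), times a lateral
  Gaussian disc of sigma `stack_radius` (default 0.5 um).
* **Optics** — anisotropic Gaussian PSF, `(sigma_z, sigma_xy)` defaulting
  to `(0.3, 0.1)` um, applied as a separable convolution (kernel
  truncated at 4 sigma, unit sum, so interior density mass is conserved
  to well under 0.5%).
* **Detection** — expected counts `brightness * density + background`,
  then Poisson shot noise, additive Gaussian read noise
  (`read_noise_sd`), clamping at zero, and digitization to integer
  counts. Defaults: brightness 300 counts per unit density, background 5,
  read noise SD 2. These put the dual-label control near its ceiling
  (mean thresholded r about 0.95) with graded decay to near zero at
  1 um axial offset — the dynamic range seen in measured bar charts of
  bright fusion-protein imaging. The default grid is 64 x 256 x 256
  voxels at (0.2, 0.1, 0.1) um spacing — 0.2-um optical sections over a
  ribbon-scale field.
* **Determinism** — every draw derives from the scene seed via a fixed
  affine hash mod 2^31 - 1: geometry from `hash(seed, 0)`, channel-i
  noise from `hash(seed, i)`; panels give pair p / cell c the seed
  `hash(base_seed, p * 100003 + c)`. Any single cell is reproducible in
  isolation, and rendering never touches the caller's RNG state.
* **Guard rails** — a scene errors out if more than 1% of a channel's
  blurred density mass lies within the 3-sigma PSF margin of the grid
  border, preventing silently truncated ribbons.

What the generator does *not* emulate: pinhole crosstalk, photobleaching,
stage drift, chromatic misregistration, cell-to-cell expression-level
variation beyond Poisson statistics, or non-Golgi background structures.
Passing the validation studies therefore shows the *measurement chain* is
correct and well-calibrated on images whose statistical structure matches
its assumptions — it does not by itself validate biological conclusions
drawn from any particular real dataset.

## Validation studies and problem sizes

The test suite ties every estimator to an independent oracle (two-pass
correlation, exhaustive threshold scans, dense eigen-decomposition,
textbook t formulas, the multcomp reference implementation for Dunnett)
and then runs simulation studies at a reduced 32 x 128 x 128 grid, chosen
so the whole suite completes on a single CPU in well under half an hour:

* monotonicity of mean thresholded r over axial offsets
  {0, 0.2, 0.4, 0.6, 0.8, 1.0} um, 10 seeded cells per offset;
* the dual-label ceiling: mean r(X, X) above every mean r(X, Y) with
  offset >= 0.3 um;
* atlas recovery: 6 enzymes at axial positions
  {0, 0.1, 0.2, 0.35, 0.5, 0.7} um, 8 cells per pair, 20 base seeds —
  the PC1 ordering must match the ground-truth axial ordering
  (|Spearman| = 1) in at least 19 of 20 panels;
* statistical calibration: 2000-replicate null simulation (5 groups,
  n = 10) holding the family-wise error at 0.05 ± 0.015.

`scripts/acceptance.R` recomputes the headline numbers of these studies
from scratch at a caller-supplied seed.

## Known limitations

* `d = 1 - r` dissimilarities are not Euclidean; SMACOF finds the best
  3D least-squares compromise, and residual stress is reported rather
  than hidden.
* The Costes scan assumes a positive association between channels exists
  at all; fully independent channels typically converge (the below-set
  correlation crosses zero almost immediately), but anti-correlated
  channels are rejected by design.
* nMDP statistics depend on the segmentation method; both Otsu and
  maximum-entropy foregrounds are first-class and the choice is recorded
  in every result row.
* The Dunnett implementation assumes equal group variances, as the
  classic test does.
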