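# golgiatlas

Quantitative 3D colocalization analysis for mapping where enzymes sit
within the Golgi stack.

Golgi glycosyltransferases occupy overlapping but distinct bands along the
cis-to-trans axis. Dual-label 3D confocal imaging can resolve those
differences statistically even when they are below the optical axial
resolution: image two labeled enzymes in the same cell, measure how well
their voxel intensities co-vary, repeat over cells and over all enzyme
pairs, and summarize the panel as a 2D "atlas" in which distance between
enzymes reflects how differently they localize.

The package implements the full measurement chain:

* **Costes automatic thresholding** — orthogonal regression
  `B = slope·A + intercept` plus a scan for the largest threshold whose
  below-threshold voxels are uncorrelated — followed by the **thresholded
  voxel Pearson correlation** `r` over the signal set.
* **Otsu and maximum-entropy (Kapur) segmentation** feeding the
  **normalized mean deviation product (nMDP)** colormap,

  nMDP(x) = (A(x) − Ā)(B(x) − B̄) / ((A_max − Ā)(B_max − B̄)),

  with the summary fractions Icorr (positive-nMDP voxels) and
  Inega-corr = 1 − Icorr.
* **Group statistics**: per-pair mean ± SEM, classic equal-variance
  Dunnett many-to-one comparisons (family-wise p from the joint
  multivariate t), unpaired pooled t-tests, significance stars.
* **The atlas**: mean pairwise correlations → dissimilarities
  d = 1 − r̄ → 3D metric MDS (SMACOF stress majorization, seeded
  restarts) → 2D PCA projection with explained-variance diagnostics.
* **A seeded synthetic generator** of ground-truthed two-channel
  Golgi-ribbon volumes (ministacks along a curve, anisotropic Gaussian
  PSF, Poisson + read noise) used to validate the chain end to end, plus
  TIFF volume I/O with voxel-size metadata and line-profile extraction.

Everything downstream of the voxel arrays is tidy: measurement tables are
tibbles, fitted atlas objects have `tidy()`, `glance()` and `autoplot()`
methods, and the pipeline composes with the pipe.

## Worked example

Render one synthetic cell with two trans-Golgi enzymes offset by 0.3 µm
along the stack axis, then run the full per-cell analysis:

```r
library(golgiatlas)

cfg <- scene_config(grid_shape = c(32L, 128L, 128L), seed = 7L)
scene <- render_cell(cfg, list(enzyme_profile("B4GALT1", 0.0),
                               enzyme_profile("ST6GAL1", 0.3)))
res <- colocalize_pair(scene)
res$measurement[c("label_a", "label_b", "r", "n_voxels", "t_a", "icorr")]
#>   label_a label_b     r n_voxels t_a  icorr
#> 1 B4GALT1 ST6GAL1 0.832   177677   8 0.6493
res$nmdp
#> <nmdp_result> 7938 foreground voxels (otsu), Icorr = 0.649, Inega-corr = 0.351
```

Reading the row: the Costes scan accepted the threshold `t_a = 8` counts
(the largest level whose below-threshold voxels are uncorrelated), and the
Pearson correlation over the 177,677 signal voxels is `r = 0.83` — high,
because a 0.3-µm offset is well inside the axial PSF, but reliably below
the dual-label control ceiling (≈ 0.95 under the same settings). Of the
Otsu-foreground voxels, 65% have positively correlated deviations
(Icorr), 35% not (Inega-corr).

Scaling up, `render_panel()` renders all enzyme pairs over many cells,
`colocalize_scenes()` gives one tibble row per cell, and `make_atlas()`
turns that table into the embedding; `autoplot(atlas)` draws the labeled
PC1/PC2 map. `run_demo(out_dir, seed)` runs the whole chain —
simulate → colocalize → stats → atlas — writing `truth.csv`, `coloc.csv`,
`stats.csv`, `distances.csv`, `embedding.csv`, `atlas.png` and a
structured log; a thin CLI over the same functions lives at
`inst/cli/golgi-atlas.R`.

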