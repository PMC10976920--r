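---
title: "Lung-graph radiomics for fibrotic ILD: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lung-graph radiomics for fibrotic ILD: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the representation

Fibrotic interstitial lung disease (f-ILD) shows on HRCT as reticulation,
architectural distortion and honeycombing, predominantly basal and
subpleural; inflammation-dominant, non-fibrotic ILD tends instead toward
smooth ground-glass attenuation. fibrograph classifies a chest CT as
fibrotic or non-fibrotic by summarising *where* and *how variably* texture
expresses itself across the lung, rather than pooling the whole lung into
one region of interest.

The pipeline is:

1. **Isotropic resampling** to 1 mm voxels (trilinear; nearest-neighbour
   for masks). Output shape is `round(extent / target)` per axis with the
   origin preserved; the interpolation kernel is a design choice, as only
   the 1 mm target is fixed by the method.
2. **Lung segmentation** by rule: threshold at -320 HU, drop air
   components touching the volume border, keep the two largest internal
   components, fill holes, label left/right by centroid. This is a
   deterministic stand-in for a learned segmenter; the phantoms carry
   ground-truth masks, and the rule recovers them (Dice is checked >= 0.95
   in the tests).
3. **36-region geometric atlas.** Per lung: three axial slabs at the 1/3
   and 2/3 voxel-count quantiles of the z-coordinates, an
   anterior/posterior split at each slab's median y, and three concentric
   shells by tertiles of the Euclidean distance (mm) to the lung boundary.
   2 lungs x 3 slabs x 2 halves x 3 shells = 36. The factorisation was an
   open design point: this one respects the basal/peripheral predominance
   of fibrosis, needs no registration, and keeps slab volumes near-equal
   in irregular lungs because boundaries are computed on voxel counts, not
   bounding boxes. Boundary placement minimises the deviation from the
   ideal count, so slab counts differ by at most the largest single-slice
   count; distance ties break toward the more central shell. Empty regions
   (e.g. resected lungs) are retained as named, absent nodes.
4. **1004-feature catalog per region**: 17 first-order, 23 GLCM, 16 GLRLM,
   15 GLSZM, 5 NGTDM and 14 GLDM features on each of 11 image types
   (original, Laplacian-of-Gaussian at sigma = 1 and 3 mm, and the eight
   sub-bands of a one-level undecimated coiflet-1 wavelet transform), plus
   14 shape features on the original geometry:
   11 x 90 + 14 = 1004. Feature definitions follow the IBSI conventions;
   the exact name lists are fixed in `build_catalog()` so that the
   per-family totals are exactly 187/14/253/176/165/55/154.
5. **Lung graphs and the descriptor.** Each catalog feature evaluated on
   all atlas regions forms a graph of at most 36 nodes. Ten statistics
   summarise each graph — max, min, median, p10, p90, mean, population SD,
   an interquartile range, skewness (g1) and excess kurtosis (g2) — and
   their concatenation over the catalog gives the per-scan descriptor,
   10 x 1004 = 10040 elements.
6. **Two-step selection** on training scans only: a two-sided
   Mann-Whitney U test per element between the classes, retention of the
   top 1% by ascending p (k = floor(0.01 D), stable ties), then greedy
   pruning in ascending-p order so no surviving pair has |Pearson r| >
   0.85 — the larger-p member of an offending pair is always the one
   removed.
7. **Classifier zoo with grouped five-fold CV**: gradient-boosted trees,
   random forest, extremely randomised trees, kNN (uniform and distance
   weights), a one-hidden-layer MLP, ridge logistic regression and an
   RBF-SVM, each with a small fixed hyper-parameter grid. Folds are
   stratified by class and grouped by patient, so no patient's scans span
   folds. Models are ranked by the mean of fold AUCs; the **weighted
   ensemble** is built by greedy forward selection with replacement on the
   pooled out-of-fold probabilities (25 steps, ties to the lower model
   index), which guarantees the ensemble's out-of-fold AUC is at least the
   best single model's.
8. **Evaluation** over five patient-grouped 80/20 random splits, at scan
   level and at patient level (arithmetic mean of a patient's scan
   probabilities), with AUC, accuracy, sensitivity, specificity, PPV and
   NPV at threshold 0.5, 95% bootstrap CIs, and a DeLong test comparing
   the ensemble against the best single model on each test set.

## Conventions that required a decision

- **Interquartile range of a graph.** The descriptor's eighth statistic is
  implemented as `percentile(75) - percentile(15)`, exactly as the method
  defines it, even though p75 - p25 is the conventional IQR; a
  `iqr_variant = "p75-p25"` switch restores the convention. Percentiles
  use linear interpolation between closest ranks (`index = q (n-1)`,
  R type 7). Constant graphs define SD = IQR = 0 and skewness/kurtosis 0.
- **Discretisation.** Fixed bin width of 25 HU on the original and LoG
  images (min-referenced, so levels are shift-invariant); fixed 16 bins on
  wavelet bands, whose ranges are not HU-scaled. Both are conventional
  radiomics defaults; the method itself does not fix them.
- **GLCM/GLRLM aggregation** averages feature values over the 13 unique 3D
  directions at distance 1, skipping directions with no pairs. GLSZM, GLDM
  and NGTDM use 26-connectivity. Degenerate denominators return defined
  sentinels: NGTDM coarseness of a constant region is 1e6 (maximal
  coarseness), ratio features with empty numerators are 0, GLCM
  correlation of a one-level region is 1. GLDM dependence is stored as
  (number of dependent neighbours + 1) so size weights stay positive.
- **Shape features** are meshless voxel approximations: surface area by
  exposed-face counting, axis lengths from the voxel-coordinate PCA
  (4 sqrt(lambda)), maximum diameters by brute force over boundary voxels,
  and a mesh-volume surrogate that counts boundary voxels at half weight.
- **Selection order.** The pruning order (ascending p of the better
  member) and greedy removal are not fixed by the method's description;
  ascending-p greedy is deterministic and favours the most significant
  elements, which matches the stated removal criterion.
- **Threshold ties.** A probability exactly at 0.5 is classified positive.
- **Bootstrap unit.** CIs resample patients, not scans, to respect
  within-patient correlation; a resample that loses a class is redrawn and
  counted. The per-class 80/20 patient allocation rounds to nearest with
  at least one test patient per class.
- **Absent regions** are omitted from a graph's node set (not imputed as
  zeros); statistics require at least 4 present nodes.

## The phantom generator

No public cohort exists for this task, so validation runs on seeded
synthetic chest phantoms that reproduce the *class-conditional texture
structure* the pipeline assumes:

- two half-ellipsoidal lungs mirrored about the mid-sagittal plane with a
  4-voxel gap, inside a soft-tissue thorax (40 HU) surrounded by air; a
  tissue shell of at least 2.5 mm is enforced so threshold segmentation is
  well-posed at any grid size;
- parenchyma at -850 HU with 20 HU Gaussian noise;
- **fibrotic class**: a thresholded |sin| product lattice of septal walls
  (default amplitude 250 HU, period 6 mm) plus Poisson-disk-sampled
  honeycomb micro-cysts (air-filled, 3 mm radius, +100 HU walls), both
  weighted toward the lung base and peripheral rind by two gradient
  parameters in [0, 1] (default 0.7);
- **non-fibrotic class**: 3-6 large Gaussian ground-glass blobs (default
  120 HU, 12 mm scale) — a smooth, first-order-shifting but texture-weak
  signal.

All randomness flows through per-component streams derived from one seed,
so identical configs are bit-identical, and blob geometry is independent
of amplitude values (the ground-glass intensity shift is exactly linear in
its amplitude). Per-scan seeds are derived deterministically from the
master seed and patient/scan indices.

The defaults are deliberate: amplitudes are large relative to the noise
floor so that a correctly implemented pipeline separates the classes at
desk scale, and the basal/peripheral weighting reproduces the spatial
prior that makes the 36-region graph representation informative. The
phantoms do **not** emulate airways, vessels, lobar anatomy, scanner
reconstruction kernels, motion artifacts, or the partial-volume and
intensity-calibration variability of real HRCT. Passing tests therefore
demonstrate correctness of the machinery and recoverability of a planted
spatial-texture signal — not clinical performance; the published
operating characteristics on real cohorts are outside what synthetic data
can certify.

## Problem sizes and runtime choices

The validation cohort is 40 patients with 1-5 scans each (uniform), 50%
fibrotic, at 96^3 voxels and 1 mm spacing — large enough for 5 grouped
80/20 splits with five-fold CV inside each training set, small enough to
run on one CPU in minutes. End-to-end checks use the original-image
catalog (104 features, 1040 descriptor elements), which carries the
planted signal; the full 11-image catalog is exercised per scan for the
dimension checks. Bootstrap CIs in the test harness use 200 replicates
(the package default is 1000); CI width is separately validated against
the binomial closed form at 1000 replicates. Texture matrices, connected
components, the Euclidean distance transform, separable convolution and
resampling are implemented in C++ (Rcpp); everything else is base R.

## Known limitations

- The geometric atlas is one of many 36-region factorisations; the
  original rule set behind "36 sub-regions" is not public, so
  cross-implementation region correspondence is not guaranteed.
- Feature values follow IBSI definitions but are not bit-compatible with
  any specific reference implementation (different resegmentation,
  interpolation and aggregation defaults); the catalog's name lists are
  fixed to reproduce the published per-family counts.
- The zoo is a representative, dependency-light stand-in for an AutoML
  stack; model identities and hyper-parameter search differ.
- `mannwhitney_p` uses the exact distribution only for combined samples of
  at most 20 without ties; larger samples use the tie- and
  continuity-corrected normal approximation.
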