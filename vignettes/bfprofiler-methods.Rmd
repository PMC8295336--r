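---
title: "Label-free discrimination of single-gene mutants from bright-field texture profiles"
author: "BFProfiler authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free discrimination of single-gene mutants from bright-field texture profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BFProfiler)
```

## The problem

Bright-field (BF) microscopy images unlabeled cells with low contrast, yet
they carry information about intracellular structure: darker connected
regions ("clumps") inside a cellular region act as a proxy for organelles
and other dense structures. BFProfiler implements a complete analysis that
asks whether cells carrying a single-gene knockout can be told apart from
their parental wild-type line using only BF texture, and whether mutants of
functionally related genes (paralog pairs of the ubiquitin–proteasome
system: PSMA2/PSMA7, PSMB5/PSMB6, PSME1/PSME2, UBQLN1/UBQLN2) leave
similar morphological signatures.

The pipeline is: synthetic paired BF/nuclear-stain image generation with
ground truth → nucleus detection and cell cropping → a fixed
296-dimensional texture profile per cell → wild-type-referenced
standardization with outlier handling and clone pooling → L1-regularized
logistic discrimination evaluated by nested tenfold cross-validation →
hierarchical clustering of the per-genotype regression-coefficient
profiles.

## The discriminative model

For a cell with standardized feature vector $x \in \mathbb{R}^{296}$ and
label $y \in \{0, 1\}$ (1 = mutant), the model is logistic regression with
an L1 penalty on the coefficients:

$$\hat\beta, \hat\alpha \;=\; \arg\min_{\beta,\alpha}\;
\frac{1}{n}\sum_{i=1}^{n}\Big[\log\!\big(1 + e^{\eta_i}\big) - y_i\,\eta_i\Big]
\;+\; \lambda \lVert \beta \rVert_1,
\qquad \eta_i = \beta^\top x_i + \alpha .$$

The linear predictor $\eta$ and the posterior probability
$\sigma(\eta) = 1/(1 + e^{-\eta})$ score each cell; the penalty $\lambda$
sets many coefficients exactly to zero, so the nonzero set is a feature
selection and the coefficient vector is the genotype's *morphological
profile*. We minimize the penalized logistic deviance (the standard
lasso-logistic objective) rather than a squared error around the sigmoid:
the deviance is convex, is what mainstream lasso solvers optimize, and is
consistent with reporting posterior probabilities.

The solver is a proximal-Newton coordinate descent written for this
package (`src/lasso.cpp`): an outer iteratively-reweighted loop builds the
local weighted quadratic model, an inner cyclic coordinate descent solves
the penalized quadratic over a screened feature set (sequential strong
rule with a full KKT check per $\lambda$, so screening is exact), and a
backtracking step toward the previous iterate guarantees that the recorded
objective trace never increases. Warm starts are used along a decreasing
$\lambda$ path. `lambdaMax()` is computed in closed form from the gradient
at the intercept-only model, and the default grid is 100 log-spaced values
spanning four decades below it. Two standard path truncations are applied
inside cross-validation only: the path stops once the fit explains 99.9%
of the null deviance or once successive $\lambda$ steps improve the
deviance by less than $10^{-5}$ of the null deviance (the overfit tail;
remaining grid points inherit the last solution). `fitL1Logistic()` at a
single $\lambda$ never truncates.

Accuracy is estimated by stratified nested tenfold cross-validation
(`nestedCV()`): the inner tenfold chooses $\lambda$ by minimum mean
validation deviance (the `lambda.min` rule — the selection criterion was
an open choice; deviance is the natural companion of the fitting
objective), the model is refit on the outer training split at that
$\lambda$, and the held-out fold is scored by ROC/AUC. The AUC is the
tie-corrected Mann–Whitney statistic divided by $n_1 n_0$, identical to
the trapezoidal area under the step ROC. The coefficient profile used for
clustering comes from a cross-validated full-data refit (`fitModelCV()`);
aggregating over folds would average incommensurate sparse supports.

Two solver tolerances are exposed: `tol` for refits at the chosen penalty
and `cvTol` for the inner selection-only path fits, which only need
validation deviances and therefore tolerate a looser setting.

## The 296-feature texture schema

The proprietary extractor that inspired the dimensionality publishes no
feature definitions, so the schema here is a fully documented
reconstruction fixed at 296 entries (`featureSchema()`):

* **Per-threshold clump morphology** (8 thresholds × 26 = 208). For each
  threshold $\tau \in \{0.1, \dots, 0.8\}$ of the crop's own min–max
  intensity range, pixels below $\min + \tau(\max - \min)$ are selected,
  8-connected components of at least 5 px are identified as clumps, and 19
  clump statistics (count, density, total/mean/SD/min/max area, equivalent
  diameters, perimeters, noncircularity, bounding-box extent and aspect)
  plus 7 whole-foreground measures (size, size fraction, perimeter,
  thinness ratio, bounding-box fill and extents) are recorded.
* **Across-threshold summaries** (2 × 26 = 52): the sample mean and SD of
  each measurement over the ladder. `tau_mean_n_clumps`,
  `tau_mean_mean_clump_area` and `tau_mean_mean_noncircularity` are the
  named "sample mean of number of clumps / average clump area / average
  noncircularity" features that the analysis highlights.
* **Intensity statistics** (18) of the raw crop and **gradient
  statistics** (18) of its Sobel gradient magnitude: mean, SD, moment
  skewness, excess kurtosis, min, max, range, median, eight deciles,
  interdecile range and IQR.

Conventions that make every number exactly reproducible: perimeter is the
count of exposed pixel edges (city-block boundary), noncircularity is
$\max(0,\, 1 - 4\pi A / P^2)$ and thinness its complement $4\pi A / P^2$,
an empty clump set contributes zeros (never missing values), and a
constant crop zeroes the clump and shape families while the intensity
family takes its degenerate values (SD, skewness and kurtosis defined as
0). Per-crop min–max normalization of the thresholds makes the clump
families invariant to illumination offset and gain. Whether the original
thresholds were absolute or relative is unstated in the source analysis;
relative thresholds were chosen precisely for that invariance. Equally,
"size" is read as pixel area (the equivalent-diameter features carry the
alternative reading).

The preprocessing filters `blur`, `edge_enhance` and `sharpen`
(`applyFilter()`) use the classical image-library kernel constants (5×5
ring mean /16; 3×3 center-10 /2; 3×3 center-32 /16), with reflected
borders; all three sum to one. `filterEffectExperiment()` measures their
effect on discrimination accuracy.

## The synthetic data generator

There is no public accession for the original images, so the generator is
a first-class, tested module that emulates the statistical structure the
analysis depends on — not a photorealistic microscope model.

Each cell is a disk of radius 40 px whose body is 300 gray levels darker
than a 16-bit background (mean 30000, Gaussian noise SD 200), containing
$k \sim \text{Poisson}(\text{rate})$ elliptical clumps with log-normal
pixel area (log-mean $\log 30$, log-SD 0.45), a genotype-specific axis
ratio, and a genotype-specific darkness (6000 gray levels below
background for the wild type). Clumps are placed uniformly in the
perinuclear region (inner 35% of the cell radius) — biologically, dense
organelle structure concentrates near the nucleus, and practically this
guarantees that a nucleus-anchored crop captures the signal. Clumps are
rasterized with a one-pixel gap so 8-connected components never merge;
degenerate draws (too small after rasterization, outside the cell,
overlapping) are resampled and logged. The paired nuclear channel holds a
2-D Gaussian blob (SD 8 px, amplitude 20000 over a background of 500),
bright enough that the classical Otsu-plus-components detector is nearly
perfect, isolating the downstream stages from detection error.

Populations spread cells over fields with rejection-sampled centers (no
overlap), 25 fields of 27 cells matching the original screen's layout at
full scale; the two clones of a genotype differ by a small additive
offset (±0.15) on the clump rate and are screened as separate populations
before pooling. A single master seed drives everything through
deterministic per-field child seeds.

The default nine-genotype panel encodes one phenotype axis per paralog
pair, shared in direction within the pair as the clustering analysis
presumes: PSMA2/PSMA7 increase clump count (rates 5.0/5.5 vs 3);
PSMB5/PSMB6 show an aggregation phenotype — fewer but larger clumps
(rates 2.0/1.8, log-area +0.55/+0.60); PSME1/PSME2 elongate clumps (axis
ratios 2.2/2.5 vs 1.2); UBQLN1/UBQLN2 darken them (7800/8200 vs 6000).
Magnitudes were chosen once so that per-genotype AUCs span roughly
0.75–1.0 at the package's scaled-down population sizes — stronger than
the weakest effects in a full-scale screen, deliberately, because the
bundled experiments run at roughly a third of the original cell counts
and the pair-recovery analysis needs stable coefficient profiles at that
size. Distinct parameter axes per pair are what make pair recovery a
property of the method rather than luck; axes that load on overlapping
feature families (e.g. pure count-up vs pure area-up, both of which raise
total clump area) measurably confuse the profile correlation.

What the generator does *not* emulate: optics (PSF, shading, debris,
focus drift), touching cells, plate and batch effects, heavy-tailed
non-Gaussian noise, or any feature correlation structure beyond what the
clump geometry induces. Passing tests therefore demonstrate that the
pipeline recovers planted structure of this kind — they do not certify
performance on real micrographs.

`generateFeatureTable()` is a model-level shortcut past the imaging
stages: wild-type cells are equicorrelated standard normal over 296
features and mutants add mean shifts at chosen indices. With no shift the
classes are exchangeable, giving an exact null for calibration; a single
feature shifted by $\delta$ has closed-form AUC $\Phi(\delta/\sqrt2)$,
giving an oracle for signal recovery.

## Preprocessing

Features are standardized by the mean and SD (denominator $n-1$) of the
raw wild-type population, mutant and wild-type alike, so values are
deviations from the wild type in wild-type SD units. Outliers are then
handled per population at the 3-SD cutoff, and the two clones of each
genotype are pooled afterwards — reference statistics from raw wild type,
then standardize, then outlier handling, then pool. Zero-SD features
standardize to 0 and are excluded from outlier flagging.

Whether the original analysis removed whole cells or individual values at
the cutoff is ambiguous; `removeOutliers()` implements both readings.
`drop_cell` (the module default) removes any cell exceeding the cutoff in
at least one feature — at 296 independent Gaussian features that already
removes $1 - (1 - 0.0027)^{296} \approx 55\%$ of perfectly well-behaved
cells, and with heavy-tailed image features it removes essentially all of
them. The pipeline therefore defaults to `clip`, which truncates
offending values to ±3 and keeps every cell; both policies log every
flagged (cell, feature, z) triple.

## Profile clustering

One row per mutant genotype of full-data-refit coefficients (exact zeros
for unselected features, no row scaling) forms the profile matrix.
Similarity is Pearson's correlation between rows; clustering is
agglomerative complete linkage on $1 - r$ (`stats::hclust`), whose merge
heights are non-decreasing by construction (asserted on every run). The
heatmap's feature axis is clustered with the same metric and linkage,
with all-zero columns dropped from the ordering only. Paralog-pair
specific features are those with positive coefficients in both pair
members and zero-or-negative coefficients in every other mutant (plus the
symmetric negative variant).

## Numerical and degenerate-input choices

* Boxes and coordinates are 0-based, row-major, half-open everywhere.
* Nucleus boxes are expanded by 50% of their height/width per side before
  cropping (the expansion the source analysis used is unstated; 0.5 makes
  the crop capture the perinuclear clump field of the generator); crops
  that would cross the field border are dropped rather than truncated.
* Greedy nearest-center matching against truth is one-to-one under a
  20 px cap; on well-separated cells it coincides with the exhaustive
  optimal assignment (tested).
* The Mann–Whitney test is computed by exact enumeration (tie-safe) for
  combined samples up to 12 and by the tie-corrected normal approximation
  without continuity correction above that.
* Fold assignment is stratified and seeded; score ties in the AUC carry
  half weight (U-statistic convention).
* Solver non-convergence raises an error carrying the objective trace; a
  line search stalled at machine precision counts as converged.

## Problem sizes of the bundled experiments

The packaged experiment (`experimentConfig()` defaults) runs the full
nine-genotype panel at 75 cells per clone (150 per genotype after
pooling) in 512×512 fields of 10 cells — roughly a fifth of the original
screen's >670 cells per genotype; large enough that the sparse
coefficient profiles of paralogous mutants overlap reproducibly, which
the pair-recovery analysis needs — with nested 10×10 cross-validation
over the 100-point penalty grid. The test suite's calibration and
recovery experiments use 500 cells per class at the full 296-feature
width, 10–20 seeded replicates each, and the truth-recovery check uses
500 single-cell images. These sizes are the package's choice of
desk-scale defaults; every size is a config parameter and scales up
unchanged.

## Known limitations

* The 296-feature schema is a documented reconstruction matching the
  published dimensionality and the named clump features; it is not the
  proprietary extractor, and absolute coefficient values are not
  comparable to the original study's.
* The nucleus detector is a classical threshold-and-components stand-in
  tuned to the generator's idealized nuclear blobs; real Hoechst images
  with touching nuclei would need a learned detector or watershed
  splitting (out of scope).
* AUCs on the synthetic panel reflect the generator's planted effect
  sizes, not any biological effect size.
* `drop_cell` outlier removal interacts badly with wide feature tables
  (see above); conclusions drawn under that policy at full width rest on
  very aggressive cell filtering.
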