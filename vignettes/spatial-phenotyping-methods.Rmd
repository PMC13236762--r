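---
title: "Methods: spatial phenotyping of smFISH spots and EV miRNA panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial phenotyping of smFISH spots and EV miRNA panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fishpheno)
```

## Scope and model

`fishpheno` quantifies where single-molecule FISH (smFISH) spots —
individual precursor-miRNA molecules rendered as diffraction-limited
puncta — sit inside segmented beta cells, classifies the cells' disease
state (non-diabetic control, islet-autoantibody positive, recent-onset
type 1 diabetes) from those spatial statistics, and evaluates panels of
extracellular-vesicle miRNAs in cohort abundance tables. Segmentation is
an input: the contribution starts downstream of cell outlining, at spot
detection, compartment assignment, feature extraction, classification and
panel evaluation. Every stage is driven by a synthetic generator with
known ground truth, so each statistic can be checked against the
parameters that produced the data.

## The synthetic generator

**Geometry.** Cells are ellipses with concentric elliptical nuclei.
Real beta cells are irregular, but the analysis only requires valid nested
regions, and ellipses make areas, ray lengths and boundary distances exact
for testing (point-to-ellipse distance is solved by bisection on the
closest-point equations; the boundary-band area uses the inner Steiner
formula `wP - pi w^2`, exact while the band width stays below the minimum
curvature radius `b^2/a`). Default scale: cell semi-major axes of 4–6 µm
at 100 nm/pixel, giving 8–12 µm cells with 4–8 µm nuclei — the scale of
human beta cells. At 100 nm/pixel the 457 nm reference radius of the
clustering feature is ≈ 4.57 px. The nucleus occupies 20–50% of the cell
area. Placement rejects overlapping bounding circles, so cells are
guaranteed disjoint and never touch the canvas border.

**Spot patterns.** Per cell the spot count is Poisson with mean
`mean_spots_per_cell`, and each spot is nuclear with probability
`nuclear_fraction`. Placement within a compartment is either uniform
(CSR) or a Thomas-type parent–offspring process: parents are Poisson with
intensity `cluster_parent_intensity` (default 0.3 per µm²) over the
compartment, realised spots are allocated uniformly across parents and
scattered isotropically with `cluster_sigma_nm` (default 200 nm),
rejection-resampled to stay inside the compartment. Conditioning the
total on the Poisson draw — rather than letting the parent process set
the count — keeps expression (feature group 1) statistically decoupled
from clustering (group 3), so classifier contrasts can isolate purely
spatial signal; with zero parents the pattern is empty, as a cluster
process admits. Boundary aggregation is generated by relocating a
`boundary_enrichment` fraction of nuclear spots uniformly into the band
of width `band_width_nm` (default 500 nm) inside the nuclear envelope,
which directly controls the group-4 statistic for recovery tests.

The per-group presets (control: 40 spots, 40% nuclear, CSR; AAb+: 60
spots, 50% nuclear, clustered, 15% boundary enrichment; T1D: 80 spots,
60% nuclear, clustered, 30% enrichment) encode the reported qualitative
contrasts — higher copy number, higher N/C ratio, nuclear clustering and
envelope aggregation with disease progression. The quantitative values
are package choices: the source imaging data are not deposited, so they
were fixed once at magnitudes a microscopist would call realistic and are
not tuned.

**Rendering.** The spot channel is a sum of unit-amplitude isotropic
Gaussians (PSF sigma default 1.5 px) plus constant background and optional
i.i.d. Gaussian noise; nucleus and cell-marker channels and both label
masks come from the rasterised geometry. The spot amplitude distribution
and SNR of the original assay are not published; the defaults are chosen
for testability, not photometric realism.

**Cohorts.** Abundances are log-normal:
`exp(Normal(group_log_mean, log_sd))` per sample and analyte, with the
default design mirroring the clinical cohort scale (26 control / 8 AAb+ /
20 T1D) and the five-marker panel (miR-155-5p, miR-146a-5p, miR-30c-1-3p,
miR-802, miR-124-3p) with the reported directions of change (all but
miR-124-3p up in disease). Effect sizes (1.0 natural-log unit in T1D,
0.6 in AAb+ for the affected markers, `log_sd` = 0.8) are package
choices of plausible magnitude.

## Image processing

Spot detection is Laplacian-of-Gaussian filtering at the PSF scale
(zero-sum, scale-normalised kernel; convolution via `EBImage::filter2`
with replicate boundaries), 8-neighbour local maxima thresholded at the
response median plus `threshold_sd` (default 5) robust SDs (MAD), and
separable quadratic sub-pixel refinement clamped to half a pixel. On
noise-free, well-separated spots this is exact to a few hundredths of a
pixel. Assignment takes the cell and nucleus label at the rounded
coordinate; a spot on the nucleus boundary pixel is nuclear (the label
value decides the tie). Nucleus labels found outside their cell label
raise an error rather than silently reassigning. Cells touching the image
border are flagged by `edge_cells()` and should be excluded (their Ripley
windows are truncated).

Nucleus morphology reports area (pixel count), perimeter (arc length of
the convex hull of pixel centres — exact for convex nuclei and free of
the staircase bias of boundary-pixel counting), eccentricity (from the
pixel covariance eigenvalues) and solidity (area over hull area).

## Spatial features

For `n` points in a window of area `A`, Ripley's K is

`K(r) = A / (n(n-1)) * sum over ordered pairs of 1(d_ij <= r)`

with `L(r) = sqrt(K/pi)` and `H(r) = L(r) - r`. The source analysis
describes H as the "normalised derivative" of K without a formula; `L - r`
is the standard variance-normalised transform in the Ripley literature and
makes `H = 0` in expectation under CSR, so it is adopted here. The
default edge correction is the border (reduced-sample) estimator —
reference points closer than `r` to the window boundary are dropped at
that radius — which is unbiased under CSR in any window shape, including
the elliptical nucleus, the cytoplasmic annulus and the boundary band.
The translation correction is implemented exactly for rectangular windows
and refused elsewhere. Radii run 50–1500 nm in 50 nm steps with 457 nm
inserted exactly, so the headline feature needs no interpolation.

Two numerical caveats are deliberate. First, `H` inherits a small
negative transform (Jensen) bias of order `-Var(K)/(8 pi L)` from the
square root; at 100 spots in a beta-cell nucleus this is about −2 nm,
well inside the Monte-Carlo noise of any per-cell estimate but visible in
averages over hundreds of cells. Second, for fewer than 2 points the
curve is flagged undefined and consumers impute: H features become 0 (the
CSR value), location features the deterministic grid average of the same
quantity over the cell region, and a boolean `imputed` flag is carried
into classification — low-expression cells are biologically meaningful
and must reach the classifier without NaNs.

The four feature groups per cell: (1) total/nuclear/cytoplasmic counts
and the pseudocounted N/C ratio `(n_nuc+1)/(c_cyt+1)` (finite for empty
cytoplasm, bias < 3% at 100 spots); (2) the mean and SD of the normalised
radial position — distance from the nucleus centroid over the distance to
the cell boundary along the same ray — and the mean signed distance to the
nuclear envelope (negative inside); (3) H at 457 nm for nuclear spots
(window = nucleus) and cytoplasmic spots (window = annulus), plus the
maximum nuclear H over the grid; (4) the fraction of nuclear spots within
the boundary band and H at 457 nm for band-resident spots with the band as
window. Spot intensities are carried through detection but not used by
the default features, since their role in the original feature set is
unstated.

## Classification

Cells are classified pairwise with a bagged decision-tree ensemble — a
random forest with `mtry` equal to the number of predictors, 500 trees by
default. The original study does not name its learner; bagging is a
robust, low-tuning choice that yields impurity-decrease importances for
the feature ranking. Splits are stratified 80/20 at the cell level,
matching the published design; a donor-blocked split is not implemented
because the synthetic generator has no donor structure (the cell-level
split's leakage caveat applies to real data with few donors). ROC and
AUC are computed from the held-out scores by the package's own empirical
estimator, which is algebraically the normalised Mann–Whitney U (ties as
half); `pROC` serves only as an independent cross-check in the tests.
Feature sets are audited by column prefix: `spatial_full` uses groups 1–4
plus the imputation flag, `expression_only` only group 1,
`morphology_only` only the nucleus-morphology columns. Constant columns
are dropped with a warning. No multiplicity adjustment is applied across
the three pairwise AUCs, matching how such AUCs are reported.

## Biomarker panel

`de_filter` keeps analytes with fold change ≥ 1.5 in either direction
(ratios, so down-regulation is tested against 1/1.5) and p strictly below
0.05. `group_compare` runs a one-way ANOVA across the three groups and
Mann–Whitney tests per pair, with an explicit `F = 0, p = 1` path for
data constant across groups.

`rank_ensemble` standardises the analytes and scores each by five
algorithms: LVQ (absolute separation of the class codebook prototypes,
via `class::olvq1`), DT (single `rpart` tree impurity decrease including
surrogates), RF (random-forest mean Gini decrease), SVM (absolute weights
of a linear max-margin hyperplane) and FRE. "Feature reconstruction
error" has no published definition; here it is the increase in the
least-squares error of a rank-k linear reconstruction of the data matrix
(k = min(3, p−1), via SVD) when the feature is withheld from the basis —
an unsupervised redundancy measure, flagged as an interpretation. Raw
importances are heterogeneous in scale, so each algorithm contributes a
coefficient equal to its rank position (1 = most important, ties broken by
analyte name), and the aggregate rank orders analytes by mean coefficient
— lower is better across all algorithms. Constant analytes get the worst
coefficient from every algorithm. Standardisation makes the whole ranking
invariant to affine rescaling of any analyte.

`cv_auc_bias_corrected` evaluates a panel by stratified five-fold
cross-validation of a logistic combination, averaged over 10 independent
fold partitions; the cvAUC is the mean of per-fold test AUCs. Averaging
fold AUCs (rather than pooling out-of-fold scores) matters: per-fold AUCs
are symmetric about 0.5 under the null, whereas pooled scores from folds
whose fitted coefficient signs disagree are systematically pessimistic.
The bias correction resamples samples with replacement (stratified within
group, default 10,000 bootstraps; tests use ≤ 1,000), repeats the entire
CV per resample, and reports `2·cvAUC − mean(bootstrap cvAUC)`. Within a
bootstrap replicate all copies of a duplicated sample share a CV fold;
otherwise duplicates straddle the train/test boundary and inflate every
bootstrap estimate. The 95% CI is the basic (reflected) bootstrap
interval `2·cvAUC − q(97.5%, 2.5%)`, chosen over the percentile interval
so that the reported interval always brackets the bias-corrected estimate
it accompanies; the exact influence-function estimator of the cited
small-sample cvAUC literature is not reproduced. All reported values are
clamped to [0, 1].

## Problem sizes in tests and the acceptance script

The calibration harness uses a fixed representative beta-cell geometry
(12 × 11 µm cell, 8 × 7 µm nucleus): 500 CSR nuclei at 100 spots for the
H(457 nm) null and envelope; 200 clustered cells (sigma 200 nm) for
power; 100 well-separated noise-free spots for detection fidelity; 200
cells for N/C-ratio recovery; 20 replicate cohorts of 150 cells per class
for the classifier contrast (300 per class in the single-run module
test); 100 replicate 30-per-group cohorts for planted-biomarker
recovery; and n = 1000 binormal / n = 200 null cohorts at 1,000
bootstraps for cvAUC calibration. These sizes give each check
comfortable statistical resolution while keeping a full run to a few
minutes on one CPU.

## Known limitations

* **Sub-PSF clustering does not survive rendering + detection.** With
  cluster scatter (200 nm) comparable to the PSF (150 nm at default
  pixel size), clustered molecules merge into single detected maxima:
  detected patterns lose — and can even invert — the ground-truth
  clustering, and detected copy numbers undercount dense cells (counts
  are detected maxima, not deconvolved molecule counts). The feature and
  classification stages therefore operate on spot *positions* (ground
  truth, or calls from imaging at sufficient effective resolution), and
  the detector is validated on resolvable, well-separated spots. This
  mirrors a genuine physical limit of any maxima-based smFISH pipeline.
* Ellipse geometry means the generator never exercises concave cells or
  nuclei; the mask-based code paths accept arbitrary labels, but the
  boundary-distance machinery behind the location and band features is
  analytic and assumes the elliptical model.
* Images are 2D, as in the tissue-section analysis emulated here; there
  is no 3D K function, no autofluorescence or aberration model, and no
  bivariate (cross-channel) Ripley statistic.
* Passing the synthetic checks shows the estimators recover the
  generator's truth under its assumptions (log-normal cohorts, Thomas
  clustering, uniform allocation); real tissue adds segmentation error,
  donor structure and optical artifacts that the generator deliberately
  does not model.
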