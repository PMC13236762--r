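# fishpheno

Spatial phenotyping of single-molecule FISH (smFISH) images of beta cells,
and evaluation of extracellular-vesicle (EV) miRNA biomarker panels.

## The problem

In type 1 diabetes, the miRNA content of beta cells changes under
inflammatory stress — not only in abundance, but in *where* the molecules
sit inside the cell. smFISH renders each precursor-miRNA molecule as a
diffraction-limited spot, so a single segmented cell yields a spatial point
pattern whose statistics carry disease information: total copy number, the
nuclear-to-cytoplasmic balance, sub-micron clustering, and aggregation at
the nuclear envelope. In parallel, panels of EV-borne miRNAs measured in
plasma provide a minimally invasive readout of the same biology, and need
principled ranking and cross-validated evaluation at small cohort sizes.

`fishpheno` implements both stages as a tested pipeline, driven end to end
by a synthetic-data generator with known ground truth, so every statistic
can be verified against the parameters that generated the data.

## What it computes

For a point pattern of `n` spots in a window of area `A`, Ripley's K is
estimated as

    K(r) = A / (n (n - 1)) * sum_{i != j} 1(d_ij <= r)

with a border (reduced-sample) edge correction available for the elliptical
nucleus, cytoplasm and boundary-band windows. The variance-normalised
transforms are `L(r) = sqrt(K(r)/pi)` and `H(r) = L(r) - r`, so `H = 0`
in expectation under complete spatial randomness (CSR) and `H > 0`
indicates clustering at scale `r`. Per cell, four feature groups are
extracted: expression counts and the pseudocounted N/C ratio
`(n_nuc + 1)/(n_cyt + 1)` (group 1), normalised radial locations (group 2),
`H` at the 457 nm reference radius in nucleus and cytoplasm (group 3), and
nuclear-boundary-band aggregation (group 4), plus nucleus morphology.
Cells are then classified pairwise (control vs autoantibody-positive vs
diabetic) with a bagged decision-tree ensemble, comparing spatial,
expression-only and morphology-only feature sets by ROC/AUC.

The biomarker stage ranks analytes by an ensemble of five importance
measures (LVQ, decision tree, random forest, linear SVM and feature
reconstruction error), applies the fold-change/p-value differential
expression filter, and evaluates panels by stratified five-fold
cross-validated AUC with a bootstrap bias correction
(`2 * cvAUC - mean(bootstrap cvAUC)`) and confidence interval.

## Worked example

```r
library(fishpheno)

# ground-truthed fields: CSR control cells vs clustered diabetic-phenotype
# cells with identical copy numbers and nuclear fractions
ga <- make_cell_geometry(150, seed = 3)
fa <- compute_feature_table(
  simulate_cells(ga, phenotype_params("control", 80, 0.6, "csr"),
                 seed = 4)$spots, ga)
gb <- make_cell_geometry(150, seed = 5)
fb <- compute_feature_table(
  simulate_cells(gb, phenotype_params("t1d", 80, 0.6, "clustered"),
                 seed = 6)$spots, gb)
summary(fa$g3_H_nuc_at_r457)   # CSR: centred on 0
#>     Min.  1st Qu.   Median     Mean  3rd Qu.     Max.
#> -212.850  -32.654   -1.922   -3.989   27.002  169.641
summary(fb$g3_H_nuc_at_r457)   # clustered: positive by hundreds of nm
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>     0.0   418.4   545.3   578.6   691.1  1369.0
```

Classifying the two phenotypes, which differ only in spatial structure:

```r
fb$cell_id <- fb$cell_id + 1000
labels <- rep(c("control", "t1d"), each = 150)
train_pairwise(rbind(fa, fb), labels, c("control", "t1d"), "spatial_full",
               split_seed = 1, model_seed = 1)
#> classifier_report: control vs t1d [spatial_full]
#>   AUC = 1.000, accuracy = 0.967 (train 240 / test 60)
```

while `feature_set = "expression_only"` on the same cells gives AUC 0.57,
near chance, because the disease signal here is purely spatial. The
imaging side of the pipeline (render, detect, assign) is exercised the same
way:

```r
img   <- render_image(simulate_cells(ga[1:20], phenotype_preset("control"),
                                     seed = 2), psf_sigma_px = 1.5)
spots <- detect_spots(img$spots, psf_sigma_px = 1.5, pixel_size_nm = 100)
spots <- assign_spots(spots, img$cell_labels, img$nucleus_labels, 100)
```

On the panel side:

```r
tab <- generate_cohort_table(cohort_spec(seed = 7))   # 26/8/20 cohort
rank_ensemble(tab, c("control", "t1d"), seed = 1)
cv_auc_bias_corrected(tab, c("control", "t1d"),
                      n_folds = 5, n_bootstrap = 1000, seed = 2)
#> panel_evaluation: control vs t1d (n = 46)
#>   cv AUC = 0.8920, bias-corrected = 0.9248 [0.8134, 1.0000]
```

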