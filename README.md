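# fetrad

Static amino-acid PET (FET) radiomics for the differentiation of true
glioma progression (TP) from treatment-related changes (TRC).

After therapy, gliomas often produce MRI findings that look like
progression but are benign treatment effects.  FET PET helps separate the
two: lesion uptake is quantified as the tumor-to-brain ratio,
`TBR = SUV_lesion / SUV_healthy-brain`, and the lesion is segmented by a
2D auto-contour at `TBR >= 1.6` in the transversal slice of the hottest
voxel.  Beyond the conventional parameters TBR_mean and TBR_max, the
*texture* of intra-lesion uptake carries diagnostic signal.  `fetrad`
implements the complete analysis as a tested R pipeline:

* **Quantification** — SUV conversion (`compute_suv`), 2.5 mm Gaussian
  scanner-harmonization filter (`harmonize`), background quantification
  (`background_mean`), threshold auto-contour (`autocontour_lesion`),
  TBR computation (`compute_tbr`).
* **Radiomics features** (`extract_features`) — 145 named features in
  five families: fractal (box counting), first-order statistics, 2D
  shape/size, gray-level texture matrices (GLCM / GLRLM / GLSZM,
  including *Informational Measure of Correlation 2* and *Intensity
  Non-Uniformity Normalized*), and the intensity-domain families
  recomputed on the four sub-bands of a one-level 2D Daubechies-3 wavelet
  transform.  Intensities are discretized on the TBR scale with an
  absolute bin width of 0.1; no spatial resampling.
* **Feature-selection cascade** (`select_features`) — near-zero-variance
  filter, pairwise Pearson correlation filter at |r| >= 0.9, and stepwise
  forward selection maximizing stratified 5-fold cross-validated AUC of a
  logistic model, stopping when the best candidate adds <= 0.005.
* **Models** (`run_study`) — three unpenalized logistic regressions fit
  on training data only: conventional (TBR_mean + TBR_max), radiomics
  (cascade-selected), combined (union, jointly refit).
* **Evaluation** — ROC analysis (`roc_auc`) with AUC by the rank
  identity, the maximum sensitivity-x-specificity cutoff
  (`optimal_cutoff`), DeLong or bootstrap 95% intervals (`auc_ci`), and
  Mann-Whitney / Fisher tests for group comparisons.
* **Synthetic cohorts** (`generate_phantom`, `generate_cohort`,
  `generate_feature_table`) — seeded brain-like phantoms whose lesions
  hit prescribed TBR_mean/TBR_max exactly and whose intra-lesion
  heterogeneity is a Gaussian random field, so every stage of the
  pipeline is verifiable against known ground truth without patient
  data.  NIfTI-1 input/output is supported (`read_pet_nifti`,
  `write_cohort`).

## Worked example

```r
library(fetrad)

# one heterogeneous "progression" lesion
ph  <- generate_phantom(phantom_spec(seed = 7, texture_amp = 0.3))
bg  <- background_mean(ph$volume, ph$background_roi)
seg <- autocontour_lesion(ph$volume, bg, threshold = 1.6)
seg
#> <lesion_segmentation> 134 voxels in transversal slice 12 (TBR >= 1.60, background 1.007)
unlist(compute_tbr(seg, ph$volume, bg))
#> tbr_mean  tbr_max
#> 2.277160 3.756815

fv <- extract_features(ph$volume, seg, bg)
round(fv[c("glcm_imc2", "glszm_inn", "shape_area")], 4)
#>  glcm_imc2  glszm_inn shape_area
#>     0.9811     0.0631   536.0000
```

The lesion is segmented in the slice of the hottest voxel; its TBR_max of
3.76 (target 3.7 plus measurement noise) and TBR_mean of 2.28 are the
conventional PET parameters, and `fv` is the radiomics feature vector the
selection cascade consumes.  A whole study runs as:

```r
dev  <- extract_cohort_features(generate_cohort(
          cohort_spec(n_tp = 93, n_trc = 31, seed = 1)))
sp   <- split_cohort(dev, ratio = 3, seed = 1)
run_study(sp$train, sp$validation, seed = 1)
```

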