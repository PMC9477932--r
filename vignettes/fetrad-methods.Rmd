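---
title: "Static FET PET radiomics: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Static FET PET radiomics: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetrad)
```

## The clinical problem and the analysis it motivates

After radio- or chemotherapy, gliomas frequently produce new
contrast-enhancing lesions on MRI that are either true tumor progression
(TP) or benign treatment-related changes (TRC).  Amino-acid PET with
O-(2-[18F]fluoroethyl)-L-tyrosine (FET) helps with this differential:
uptake is quantified as the tumor-to-brain ratio (TBR), the lesion SUV
divided by the mean SUV of healthy contralateral brain, and progressive
tumors tend to show higher TBR.  Beyond the two conventional parameters
TBR~mean~ and TBR~max~, the intra-lesion *texture* of uptake carries
information that is not accessible visually; radiomics turns it into
features and a classifier.

`fetrad` implements that full analysis as a reusable, tested pipeline:

1. **Quantification** — SUV conversion, optional Gaussian scanner
   harmonization, background quantification, 2D threshold auto-contour
   segmentation, TBR computation.
2. **Feature extraction** — five families: fractal, first-order,
   shape/size, gray-level texture matrices (GLCM/GLRLM/GLSZM), and the
   same intensity-domain families recomputed on the sub-bands of a
   one-level 2D wavelet transform.
3. **Feature selection** — a three-stage cascade on training data only:
   near-zero-variance filter, pairwise-correlation filter (|r| >= 0.9),
   stepwise forward selection under stratified cross-validated AUC with a
   0.005 improvement stop.
4. **Models** — three unpenalized logistic regressions: conventional
   (TBR~mean~ + TBR~max~), radiomics (cascade-selected features), and a
   combined model refit on the union.
5. **Evaluation** — ROC analysis with the maximum sens x spec cutoff rule,
   DeLong 95% confidence intervals, Mann-Whitney and Fisher tests for the
   group comparisons.

Because clinical scans cannot ship with the package, a seeded phantom and
cohort generator stands in for them.  It is a first-class, tested module:
every downstream stage is verified against data whose ground truth is
known by construction.

## Quantification conventions

**SUV.** `compute_suv()` divides tissue activity (kBq/ml) by injected
activity per gram of body weight.  With weight-proportional dosing
(3 MBq/kg) the weight cancels and SUV = kBq/ml divided by 3, which the
tests exploit as an algebraic oracle.  A volume already flagged as SUV is
refused — a silent double conversion would corrupt every TBR downstream.

**Harmonization filter.** A "2.5 mm 3D Gaussian" is read as FWHM
(sigma = 2.5/2.355 mm per axis), the convention under which PET
harmonization kernels are quoted; `interpretation = "sigma"` exposes the
alternative reading.  The filter is a separable truncated-Gaussian
convolution with boundary renormalization (normalized convolution), so a
constant volume is exactly preserved and an interior impulse keeps unit
mass.

**Segmentation.** The lesion is auto-contoured in 2D: find the hottest
voxel (ties broken by lowest linear index), take its transversal slice
(third array axis), threshold the slice at TBR >= 1.6, and keep the
8-connected component containing the hottest voxel.  Disjoint
supra-threshold islands are not lesion.  If no voxel reaches the
threshold the function returns `NULL` ("no lesion") rather than failing.
TBR~max~ and TBR~mean~ are the maximum and mean lesion SUV divided by the
background mean; by construction TBR~max~ >= TBR~mean~ >= 1.6, and
`compute_tbr()` enforces this on any segmentation it is handed.

All of this is invariant under global intensity rescaling of the scan,
which the tests check exactly (scale factor a power of two, so floating
point cooperates).

## Feature extraction conventions

**Discretization.** Lesion SUVs are converted to TBR and binned with an
absolute fixed bin width of 0.1 anchored at zero: level
g = floor(TBR/0.1) + 1, so bin 17 is [1.6, 1.7).  Absolute anchoring
keeps bins comparable across subjects; a min-anchored variant exists as
an option.  No spatial resampling is performed.  Computing on TBR rather
than raw SUV makes the 0.1 width scanner-independent; binning raw SUV
instead is available by passing `background = 1`.

**Texture matrices.** All texture analysis is 2D in the segmented slice,
matching the 2D segmentation: GLCM at distance 1 along the four in-plane
directions (symmetrized, normalized, features averaged over directions),
GLRLM along the same four directions, GLSZM with 8-connected zones.
Texture features include the two of clinical interest here —
Informational Measure of Correlation 2,
IMC2 = sqrt(1 − exp(−2(HXY2 − HXY))) with entropies in log base 2, and
the gray-level (intensity) non-uniformity normalized of the zone matrix,
INN = Σ~g~(Σ~z~ s(g,z))² / N~z~² — plus contrast, correlation, joint
entropy, energy, homogeneity, IMC1, run-length and zone-size statistics.
The implementations are validated against exhaustive enumeration oracles
(all pairs, all runs, recursive flood fill) on every 2x2 ROI and strip
with up to three levels and on seeded random 3x4/4x4 ROIs, exactly.

**Degenerate fallbacks.** A single-gray-level ROI yields IMC1 = IMC2 =
correlation = 0, entropies 0, uniformity 1; a single-voxel sub-band ROI
takes the same continuity-limit values.  Features are therefore always
finite and the feature vector never contains missing values.

**Shape.** 2D area (voxel count x in-plane voxel area), perimeter by
marching squares at the 0.5 iso-level, circularity 4πA/P², and maximum
diameter as the largest pairwise distance between voxel centers (0 for a
single voxel — a center-to-center convention, stated explicitly because
a corner-to-corner convention would give the voxel diagonal).

**Fractal.** Box counting of the lesion boundary (dimension near 1 for
smooth contours) and differential box counting of the TBR surface
(near 2 for flat, toward 3 for rough), both as least-squares slopes over
dyadic box sizes; boxes wider than a quarter of the extent are excluded
because they measure gross size, not roughness.  Fewer than 4 boundary
pixels or fewer than two usable scales fall back to the smooth-limit
values 1 and 2.

**Wavelets.** One-level separable 2D DWT of the TBR patch around the
lesion (2-voxel context pad) with the 6-tap Daubechies-3 wavelet.
Boundary handling is symmetric (half-sample) extension rather than zero
padding: the lesion patch is small, and zero padding would manufacture
spurious detail energy at every patch border — with symmetric extension a
constant patch has exactly zero detail coefficients, which is also the
property the tests pin down.  First-order, texture and fractal (surface)
features are recomputed per sub-band on mask-restricted coefficients;
shape is not recomputed because filtering does not move the mask — the
wavelet group is therefore fractal + first-order + texture.  Sub-band
coefficients have no absolute scale, so they are discretized into 16
equal-width bins over their occupied range instead of the absolute 0.1
width.

The default full vector has 145 named features (33 on the original image
+ 28 on each of the four sub-bands), in deterministic order.

## The synthetic cohort: what it emulates and what it does not

`generate_phantom()` builds, on a 48 x 48 x 24 grid of 2 mm voxels, a
uniform brain-like background (SUV 1.0) with additive white noise
(SD 0.05 SUV), one ellipsoidal lesion (default semi-axes 16/14/12 mm —
a 2-3 cm lesion, giving ~150 in-slice voxels at PET resolution), and a
background reference ellipsoid mirrored through the mid-sagittal plane,
emulating the contralateral semioval-center placement without anatomy.

The lesion's noise-free TBR profile is a power-law of centrality,
u^p, with the exponent calibrated per lesion (by `uniroot`) so that the
hottest transversal slice has exactly the target TBR~mean~ and the
hottest voxel exactly the target TBR~max~ — the two quantities the 2D
auto-contour measures.  Heterogeneity is a Gaussian random field
(smoothed white noise) added inside the lesion, with correlation length
8 mm: PET's point-spread function makes genuinely sub-resolution texture
unobservable, so the generator plants heterogeneity at the blob scale a
scanner can actually resolve.  For textured lesions the re-pinning of
(mean, max) after adding the field lets some rim voxels fall below the
1.6 threshold, so their measured TBR~mean~ runs slightly above target;
homogeneous lesions quantify exactly.

`cohort_spec()` defaults emulate a glioma follow-up cohort at 75/25
TP/TRC prevalence with class distributions TBR~mean~ 2.1 ± 0.3 vs
1.9 ± 0.3 and TBR~max~ 3.7 ± 0.9 vs 2.8 ± 0.7 (truncated so every lesion
is detectable), and texture amplitude 0.30 ± 0.08 SUV for TP vs
0.03 ± 0.02 for TRC.  The amplitudes are conventions, not estimates: no
quantitative description of intra-lesion FET texture by class exists, and
visual inspection of such scans does not reveal one.  Per-subject seeds
derive deterministically from the master seed, so a cohort is a pure
function of its spec.

What the generator does **not** emulate: anatomy (gray/white matter,
ventricles), scanner physics (PSF, scatter, randoms, reconstruction
artifacts), non-Gaussian noise, multifocal or non-ellipsoidal lesions,
and any correlation between TBR level and texture beyond what the class
distributions impose.  Passing end-to-end tests on these phantoms shows
the *pipeline machinery* is correct and information flows are clean; it
does not certify diagnostic performance on patients.

One empirical note from the tests: with 0.1-wide TBR bins over ~150-voxel
ROIs, GLCM entropies are near saturation in both classes, so
original-image IMC2 is only a weak marker of the planted heterogeneity
in this generator, whereas zone statistics (INN) and many wavelet-domain
features separate strongly (the feature-separation test asserts INN at
p < 0.01 and that a broad set of features separates at p < 0.001).  On
patient data, where heterogeneity is not a stationary Gaussian field,
the relative ranking of features can of course differ.

## Selection, models and evaluation

The cascade runs on the training split only; the interfaces accept a
single table, so validation or test labels cannot leak in (and a test
fits the models with shuffled held-out labels to prove nothing changes).

* **Near-zero variance:** a feature is dropped if exactly constant, or if
  its most-common/second-most-common value frequency ratio is >= 19
  (95/5) *and* its distinct-value fraction is <= 10% — the widely used
  preprocessing convention, since "near zero" is otherwise undefined.
* **Correlation filter:** pairwise Pearson |r| >= 0.9; the member of the
  worst pair with the larger mean absolute correlation to everything else
  is removed, ties by column order.  The stage is idempotent and is
  tested against a naive re-implementation of the same greedy rule.
* **Forward selection:** greedy addition maximizing mean stratified
  5-fold CV AUC of an unpenalized logistic model, stopping when the best
  candidate's improvement is <= 0.005 (the strictly-greater reading of
  "does not add more than 0.005").  The empty model scores AUC 0.5.
  k = 5 is a standard default, exposed as a parameter.  On all-noise
  tables (n = 200, p = 20) the stop rule keeps <= 2 features in >= 90% of
  seeds; a planted separating feature is picked first in >= 95%.

Features are standardized to training mean/SD before fitting (numerical
stability across heterogeneous feature scales; coefficients are reported
on both scales).  Complete separation is detected and stabilized by a
minimal ridge penalty, flagged on the model object.  The combined model
is a joint refit on conventional ∪ selected radiomics features (not a
stacking of model outputs) — with selection and fitting both confined to
training data, a joint refit is the cleaner reading.

ROC analysis computes AUC by the rank (Mann-Whitney) identity with ties
at half weight; the trapezoid under the returned curve equals it to
1e-12, which is asserted.  The operating cutoff maximizes sensitivity x
specificity; among ties the more specific cutoff wins (conservative
against over-calling progression, with TP as the positive class).  The
95% CI uses DeLong's placement-value variance by default, with a seeded
stratified bootstrap as the alternative and as the fallback when the AUC
is degenerate.  Because a deployed classifier carries its cutoff with it,
`run_study()` reports the test split both at its own optimal cutoff and
at the validation-derived cutoff.

## Problem sizes used in tests

The texture oracles enumerate all 2x2 ROIs and 1x4 strips over three
gray levels plus 150 seeded random 3x3/4x4 ROIs.  End-to-end properties
use 50 seeds each: the null control (identical class distributions,
texture amplitude 0, balanced 50/50 cohorts of n = 100 for training and
held-out evaluation) requires all three model AUCs in [0.35, 0.65] in at
least 95% of seeds; the planted-texture condition (amplitude 0.6 vs 0,
TBR distributions matched, 75/25 cohorts of n = 100) requires the
radiomics model to beat the conventional model in at least 90% of seeds.
Balanced classes in the null control are a design choice: they make the
permutation distribution of the AUC tightest, so the band is a statement
about the pipeline rather than about class imbalance.  DeLong coverage is
checked on 1000 null replicates at n = 200.

## Known limitations

* 2D-only texture (by design, matching the 2D segmentation); a 3D mode
  would change feature definitions, not just parameters.
* The explicit 145-feature inventory is documented and fixed, but it is
  not a name-for-name reproduction of any proprietary toolbox inventory.
* DeLong intervals are asymptotic; at very small validation sets the
  bootstrap alternative is preferable.
* The generator's texture model is stationary and Gaussian inside the
  lesion; real uptake heterogeneity (necrosis, infiltration gradients)
  is neither.
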