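---
title: "Characterising MLC position errors with dose-distribution indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterising MLC position errors with dose-distribution indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlcqa)
```

## The problem

Intensity-modulated radiotherapy (IMRT) shapes dose with a multileaf
collimator (MLC): two opposing banks of motorised leaves that form a
different aperture at every control point of every beam. Leaf-position
errors — a whole bank systematically offset by a fraction of a millimetre,
or every leaf randomly displaced — distort the delivered dose in ways that
conventional patient-specific QA metrics summarise only coarsely. This
package implements a complete, self-contained study of how such errors
imprint themselves on dose distributions: it simulates segmented-MLC plans
and doses on TG-119-like phantoms, injects controlled systematic and random
leaf errors, quantifies the dose differences with gamma analysis, the
structural similarity (SSIM) index, and a 34-feature dosiomics vector on
subtracted dose maps, screens those indices statistically, and trains gated
logistic-regression classifiers that recognise whether a dose distribution
carries an MLC position error.

Everything runs on synthetic data generated by the package itself; no
planning system, CT data, or download is required. The same functions
accept DICOM-RT Plan and Dose files, for which a minimal reader/writer
(explicit VR little endian) is included.

## The simulated study conditions

The generator's defaults encode the study conditions:

* **Cases.** Four phantom geometries echo the AAPM TG-119 roles:
  `head_and_neck` (large PTV, posterior cord, two lateral parotids),
  `prostate` (PTV with superior bladder and posterior rectum), and two
  C-shape targets wrapping a central cord with a larger (`c_shape_easy`)
  or smaller (`c_shape_hard`) gap. Masks live on a 2 mm isotropic lattice
  (default 48³ voxels, i.e. a 9.6 cm cube — desk-scale stand-ins, not
  clinical volumes).
* **Plans.** Equally spaced coplanar beams; each beam's aperture conforms
  to the PTV's beam's-eye-view outline (4 mm margin) and is modulated into
  segments by random inward leaf excursions with random MU weights. Suites
  use per-beam dose maps as the analysis unit; the study-sized
  head-and-neck suite has 36 error-free, 36 systematic-error, and 27
  random-error beams.
* **Errors.** Systematic: every leaf of one bank shifted by 0.5, 1.0, 1.5
  or 2.0 mm toward +x at every control point, restricted by default to the
  leaf pairs that are open (the pairs shaping the PTV field edge); a shift
  that would cross the opposing leaf is capped (the pair closes). Random:
  every leaf on both banks draws an independent Gaussian displacement with
  mean 0, 1, or 2 mm and sigma 1 mm; draws that would collide are simply
  re-drawn. MU weights are never altered by either injection.
* **Dose engine.** Apertures are rasterised into fluence with fractional
  voxel coverage at leaf tips (so sub-voxel shifts change the map), leaf
  transmission 2% under closed leaves, Gaussian penumbra blur of sigma
  3 mm, and a dose scale of 2 Gy (one fraction). The 3D dose is the sum
  over beams of the fluence forward-projected with exponential depth
  attenuation (0.006/mm); it is normalised so the error-free PTV mean is
  2 Gy, and error plans are computed with the *same* scale factor so dose
  differences are physical. Map noise is configurable but defaults to 0:
  the emulated workflow recalculates dose deterministically in a planning
  system, and at the 1 cGy discretisation bin even half-a-cGy of noise
  fragments the homogeneous runs that carry the systematic-error texture
  signature.

## Indices

**Gamma.** Local gamma with dose-difference tolerance as a percentage of
the local reference dose, criteria 3%/3 mm through 1%/1 mm, 10% low-dose
threshold. The search is exhaustive over a sub-voxel offset lattice
(default step 0.1 DTA within a radius of 3 DTA) with trilinear
interpolation of the evaluated grid and early termination once the distance
term alone exceeds the current best. Per-beam (single-slice) and whole-plan
3D grids use the same code path. Two behaviours matter for interpretation:
a pure edge displacement equal to the DTA sits exactly at gamma = 1 and
still *passes*, so per-beam 2D pass rates barely react to one-bank shifts;
the composite 3D dose, where every beam's edge moves in a different
patient-frame direction, is not recoverable by any single displacement and
its pass rate degrades steeply (in the bundled analysis, 3%/2 mm falls
from 0.9999 at 0.5 mm to ≈0.89 at 2.0 mm).

**SSIM.** Luminance, contrast, and structure are combined with the
conventional constants `C1 = (K1 L)^2`, `C2 = (K2 L)^2`, `C3 = C2/2`,
`K1 = 0.01`, `K2 = 0.03`, and dynamic range `L = 200` (maps are compared
in cGy, so `L` equals the fraction dose). Two window modes are first-class:
the canonical 11×11 Gaussian window (sigma 1.5), the default, and a
whole-image (`"global"`) mode, for which the constant-image closed forms
used in the tests are exact. The mode matters for the subcomponent story:
with whole-image statistics a one-bank shift changes the delivered dose
(the mean) far more than the variance, so luminance is the sensitive
subcomponent; with small windows the displaced penumbra also perturbs the
windowed variances, making contrast comparably sensitive. Zero-variance
windows need no special-casing because `s = (sxy + C3)/(sx sy + C3)` is 1
when both SDs vanish.

**Dosiomics.** Each subtracted map (error or 0.01 mm-shifted stand-in minus
error-free) is resampled to 2 mm, scaled to cGy, and discretised with bin
width 1 anchored at the map minimum (level 1 = minimum bin; subtracted maps
are negative-going, and min-anchoring makes the features invariant under
constant offsets). The 34-feature vector comprises mean intensity; histogram
skewness and excess kurtosis; six GLCM features (13 directions, distance 1,
symmetric, probability-normalised); eleven GLRLM features (run matrices per
direction, features averaged over the 13 directions); three NGLDM features
(26-neighbour gray-level difference statistics; Coarseness is capped at 1e6
for uniform volumes where its denominator vanishes); and eleven GLZLM
features (zones = 26-connected equal-level components, labelled in C++).
The exact feature identities follow LIFEx v7.1 conventions and are pinned
by `feature_manifest()`; renaming any of them is a breaking change. The
category counts (1 conventional + 2 histogram + 31 texture) constrain but
do not fully determine the set, so this manifest is the package's
interpretation of them.

**Sub-error-free maps.** Subtracting an error-free map from itself would
give identically zero, so the stand-in is the map translated 0.01 mm along
x by linear interpolation. `validate_simulated_error_free()` checks that
the stand-in is statistically indistinguishable from the original:
Spearman rho above 0.97 and a non-significant paired Wilcoxon test.

## Selection and modelling

Labels are 0 for sub-error-free rows and 1 for any error; Class-I pools
systematic and random errors against error-free, Class-II uses systematic
only, Class-III random only. Selection runs in a fixed order:

1. **Spearman correlation filter** — all pairwise rank correlations with
   Holm–Bonferroni-adjusted p-values; from each significant pair with
   |rho| > 0.8 the member with the larger mean absolute correlation to the
   remaining features is dropped (keeping the less redundant index; the
   source procedure does not specify a tie-break).
2. **Backward stepwise elimination** from the full logistic model, with
   AIC as the elimination criterion. Perfect separation — common on strongly separable synthetic
   suites — is flagged, and ridge-penalised coefficients are reported
   alongside as a stabilised reference.
3. **VIF filter** — iteratively drop the feature with the highest variance
   inflation factor while any is ≥ 4.

The classifier is plain logistic regression trained with caret's
stratified 70% split and repeated 10-fold cross-validation (10 repeats).
Held-out metrics are the rank-statistic AUC (Mann–Whitney form) and the
confusion-matrix metrics at probability threshold 0.5 with the error class
positive; the model p-value is a likelihood-ratio test against the
intercept-only model. A candidate becomes a **final model** only if AUC,
accuracy, precision, sensitivity and specificity are all ≥ 0.8 (inclusive)
and p < 0.05.

## DVH impact

`dvh_relative_difference()` reports, per structure, the relative percentage
change of mean dose, D95, and D2 between the error-free and error doses
(no single DVH scalar is canonical for this comparison, so all three are
reported), flagged against the clinical criteria: any PTV underdose, or
an OAR change of 3% or more (inclusive). On the synthetic suites the OAR
mean-dose difference grows monotonically and near-linearly with the
systematic shift (linear R² ≈ 1.0), with the 3% criterion exceeded from
about 1.5 mm.
This behaviour is why the default systematic shift acts on bank B: shifting
the positive-side bank rightward *opens* the field edge toward the
surrounding normal tissue. Shifting bank A rightward advances leaves into
the field and reduces both PTV and OAR dose instead; both are available.

## Design decisions on open points

* **Coordinates.** IEC-style beam-limiting-device coordinates in mm; bank A
  is the negative side, so `bank_a <= bank_b` is the no-collision
  invariant; "a shift to the right" is +x for whichever bank is chosen.
* **Random-error sign convention.** The per-bank means are signed so the
  mean displacement widens the field (bank A mean −mu, bank B +mu);
  `direction = "same"` gives a mean translation instead; neither
  convention is canonical, so both are supported.
* **Collision handling** differs by error type on purpose: systematic
  shifts cap deterministically (the pair closes); random draws re-draw
  until collision-free.
* **Bin width unit.** "Bin size 1" is interpreted in cGy (maps stored in
  Gy are scaled by 100 before binning), consistent with L = 200 for a
  2 Gy fraction; both the bin width and the scale are configurable.
* **Problem sizes.** Tests and the acceptance analysis use 48³ (or 40³)
  phantoms, 7–36 beams and 3–5 control points per beam — sizes chosen so
  a full pipeline run takes seconds while every stage still operates in
  its intended regime.

## What the synthetic data does and does not show

The generator reproduces the *geometric* signatures of MLC errors — edge
displacement, field widening, penumbra overlap — on smooth, homogeneous,
noiseless dose maps. It does not model tissue heterogeneity, scatter,
measurement devices, CT calibration, or plan optimisation; apertures
conform to the PTV outline rather than arising from inverse planning, so a
row-wise aperture cannot spare a central structure the way a clinically
optimised C-shape plan partially does. Consequences to keep in mind:

* Classifier metrics on these suites are essentially perfect (AUC ≈ 1).
  Passing the ≥ 0.8 gate here demonstrates that the pipeline is wired
  correctly and that the features carry the error signal, not that a
  clinical dataset would reach the same numbers.
* Sub-error-free maps quantise to a single gray level at the 1 cGy bin
  (their dynamic range under a 0.01 mm shift is a fraction of a cGy), so
  their homogeneous runs span the whole map. Run-emphasis features such as
  GLRLM_LRHGE therefore separate the classes sharply, but the *direction*
  of the difference depends on this degeneracy and should not be read as a
  clinical direction; the co-occurrence uniformity story (GLCM_Energy
  highest for error-free maps, decreasing with error) is the robust one.
* Per-beam 2D gamma is nearly blind to one-bank shifts at clinical
  criteria; use the whole-plan 3D gamma for Table-3-style trends.
* Dynamic MLC delivery and VMAT arcs are out of scope; only static
  segmented-MLC plans are modelled.

## Reproducibility

Every stochastic stage (plan modulation, random-error draws, splits, CV
folds) derives from explicit integer seeds, and a `run_experiment()` call
is a deterministic function of its `experiment_config()`; regenerating a
report with the same config and seed reproduces the output files
byte-for-byte. The numbered scripts under `analysis/` replay the full
study narrative, and `scripts/acceptance.R` recomputes the headline
quantities from scratch against the installed package.
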