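# mlcqa — characterising MLC position errors from dose-distribution indices

`mlcqa` is an R package plus analysis workflow for a question in
radiotherapy dosimetric QA: **what do multileaf-collimator (MLC)
leaf-position errors look like in a dose distribution, and can they be
recognised automatically?** It is aimed at medical physicists and
methodologists who want a fully reproducible, download-free sandbox for
dose-comparison indices: everything — plans, doses, errors — is simulated
by the package on TG-119-like phantom geometries, and the same index
machinery also accepts DICOM-RT Plan/Dose files.

## What it does

The pipeline mirrors a complete error-characterisation study:

1. **Simulate** segmented-MLC IMRT plans (beams → control points → leaf
   banks with MU weights) and 3D/per-beam doses on four phantom cases
   (head-and-neck, prostate, C-shape easy/hard) with a fluence-projection
   dose engine (2 mm grid, 3 mm penumbra, 2 Gy fraction).
2. **Inject errors**: systematic one-bank shifts (0.5–2.0 mm, capped at
   the opposing leaf) and random per-leaf Gaussian shifts
   (μ ∈ {0, 1, 2} mm, σ = 1 mm, collision-free by re-drawing). MU is never
   altered.
3. **Quantify** error-free vs error dose with
   - the **local gamma index** γ(r) = min√((Δr/DTA)² + (ΔD/δ·D_local)²)
     at 3 %/3 mm … 1 %/1 mm with a 10 % threshold (exhaustive sub-voxel
     search, C++);
   - **SSIM** = l·c·s with C₁ = (K₁L)², C₂ = (K₂L)², C₃ = C₂/2,
     K₁ = 0.01, K₂ = 0.03, L = 200, windowed or whole-image;
   - **34 dosiomics features** (mean intensity, skewness, kurtosis, and
     GLCM/GLRLM/NGLDM/GLZLM textures) from *subtracted* dose maps
     (error − error-free; the error-free class uses a 0.01 mm-shifted
     stand-in), discretised at 1 cGy bins.
4. **Select** indices: pairwise Spearman |ρ| > 0.8 removal with
   Holm–Bonferroni correction → backward stepwise elimination (AIC) →
   VIF < 4.
5. **Classify** with logistic regression (stratified 70 % split, repeated
   10-fold CV ×10); a model is *final* only if AUC, accuracy, precision,
   sensitivity and specificity are all ≥ 0.8 with p < 0.05.
6. **Relate to DVH**: relative % change of mean dose/D95/D2 per structure,
   flagged at PTV underdose or OAR ≥ 3 %.

## Worked example

```r
library(mlcqa)

phantom <- make_phantom("c_shape_easy")
plan    <- make_plan(phantom, n_beams = 9, n_control_points = 5, seed = 7)
free    <- compute_dose(plan, phantom)

err_plan <- inject_systematic(plan, systematic_error_spec(2.0))
err      <- compute_dose(err_plan, phantom, scale = free$scale)

gamma_index(free$dose, err$dose, gamma_criteria(3, 2), step_frac = 0.25)
#> <gamma_result> 3%/2 mm (local): pass rate 0.8360 over 56789 voxels

ssim_index(free$beam_maps[[1]]$values * 100, err$beam_maps[[1]]$values * 100)
#> <ssim_result> ssim=0.98545 l=0.99420 c=0.99284 s=0.99789

sub <- subtract_dose(err$beam_maps[[1]], free$beam_maps[[1]], "sub_systematic")
round(extract_features(sub)[c("Conv_MeanIntensity", "GLCM_Energy",
                              "GLRLM_LRHGE", "GLZLM_GLNU")], 4)
#> Conv_MeanIntensity        GLCM_Energy        GLRLM_LRHGE         GLZLM_GLNU
#>             1.1343             0.8103           193.8385             8.3810
```

A 2 mm one-bank shift leaves only 83.6 % of voxels passing the 3 %/2 mm
whole-plan gamma, lowers SSIM mostly through its luminance term, and
imprints the subtracted map with a net positive mean (the opened field
delivers more dose, here +1.13 cGy) and a strongly non-uniform texture
(GLCM energy 0.81 vs 1.0 for an error-free subtraction).

The numbered scripts under `analysis/` replay the whole study and write
their tables under `results/`:

```sh
Rscript analysis/01_simulate.R       # phantoms, plans, error-free doses (+DICOM)
Rscript analysis/02_inject_errors.R  # labelled error suites, MU conservation
Rscript analysis/03_indices.R        # feature table + gamma/SSIM summaries
Rscript analysis/04_models.R         # selection cascade + gated classifiers
Rscript analysis/05_dvh.R            # DVH relative differences vs error size
```

Representative output: the whole-plan 3D gamma (3 %/2 mm) falls
0.9999 / 0.9958 / 0.9720 / 0.8907 across 0.5/1/1.5/2 mm systematic shifts,
and the head-and-neck cord mean dose rises +1.24 / +2.45 / +3.64 / +4.81 %
(linear R² = 1.00), crossing the 3 % clinical criterion between 1 and
1.5 mm.

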