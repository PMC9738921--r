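# fdopamics

Dynamic ^18^F-FDOPA PET analysis for neuro-oncology: point-spread-function
deconvolution, parametric TBR/TTP imaging, IBSI-style radiomics, and a
repeated cross-validated Lasso classification harness, exercised end-to-end
on synthetic phantom cohorts with known ground truth.

## The problem

Amino-acid PET of gliomas carries diagnostic information in two channels:
the **static contrast** of the lesion, summarized as the
tumour-to-background ratio `TBR = SUV / SUVmean(healthy brain)`, and the
**kinetics** of the time-activity curve (TAC), summarized as the
time-to-peak `TTP = argmax_t TAC_ratio(t)` of the tumour TAC normalized by
the fitted healthy-brain TAC. Radiomics features extracted from TBR and TTP
parametric maps can predict molecular markers (IDH mutation, 1p/19q
codeletion) non-invasively. Scanner blur (the point-spread function, PSF)
attenuates lesion contrast in a size-dependent way; post-reconstruction PSF
deconvolution (PSFd) restores contrast at the cost of noise. The question
this package operationalizes: **does PSFd change the radiomics features,
and does it improve molecular-status classification?**

Because the underlying clinical cohorts are not distributable, the package
generates synthetic dynamic brain phantoms — 30 frames × 1 min, brain /
striatum / tumour compartments, piecewise-linear lesion kinetics with exact
ground-truth TTP and contrast, degraded by a known Gaussian PSF and
Poisson-like noise — and runs the full two-arm (with / without PSFd)
analysis on them.

At its core:

* **Richardson–Lucy deconvolution** with a Gaussian kernel
  (`est ← est · K(obs / K(est))`), flux-conserving and non-negative;
* **HYPR-LR denoising** (`frame ← C · lowpass(frame) / lowpass(C)` with
  composite `C` the time-mean of all frames);
* threshold segmentation (tumour at 1.6 × brain SUVmean, striatum at 70%
  of its SUVmax), TBR and voxel-TTP parametric maps via a constrained
  two-segment kinetic TAC fit;
* **105 IBSI-style features** per map (11 morphology via marching
  tetrahedra, 19 intensity including both 1-cm³ intensity peaks, 75
  texture: GLCM/GLRLM/GLSZM/GLDM/NGTDM);
* a leakage-free ML pipeline: z-scoring, Spearman complete-linkage feature
  agglomeration (|ρ| ≥ 0.9), Borderline-SMOTE, L1 logistic regression with
  a 300-probe log-uniform penalty search, stratified repeated 5-fold CV,
  1000-draw bootstrap CIs, permutation tests, and exact linear SHAP
  importances;
* paired Wilcoxon + Benjamini–Hochberg feature-change statistics between
  reconstruction arms, and the lesion-size dependence of the TBRmax
  change.

## Worked example

```r
library(fdopamics)

spec <- phantom_spec(
  psf_fwhm_mm = 4.5, noise_model = list(type = "poisson", scale = 0.05),
  lesions = list(lesion_spec(center = c(14, 24, 12), semi_axes = c(6, 6, 6),
                             class_label = 0L, amplitude_ratio = 2.5,
                             ttp_true = 7.5, washout_slope_true = 1.0)),
  seed = 7L)
subject <- render_subject(spec)
subject$study
#> <dynamic_study> 48 x 48 x 24 voxels, 30 frames, spacing 2x2x2 mm

no  <- analyze_subject(subject, psfd = FALSE)
yes <- analyze_subject(subject, psfd = TRUE)
round(rbind(no_psfd = no$region, psfd = yes$region), 3)
#>         TBR_mean TBR_max TBR_peak TSR_mean TSR_max TSR_peak MTV TTP_region slope_region
#> no_psfd    1.918   2.250    1.828    0.955   1.120    0.910 744        7.5       -0.556
#> psfd       2.133   2.639    1.871    0.919   1.137    0.806 936        7.5       -0.671
```

The lesion was built with a true peak contrast of 2.5 reached at 7.5 min.
After 4.5-mm blur, the measured `TBR_max` drops to 2.25; deconvolution
restores it to 2.64 (a slight overshoot is typical of Richardson–Lucy on
noisy data). The region TTP of 7.5 min recovers the ground truth exactly in
both arms — deconvolution reshapes the static contrast much more than the
kinetics, which is the central directional finding the package reproduces.
`MTV` is the 1.6-threshold volume in mm³; `slope_region` is the late washout
of the TAC ratio in h⁻¹ (negative: washing out).

Cohort-scale experiments run through `run_experiment()`:

```r
res <- run_experiment(experiment_config(n_subjects = 40, seed = 1),
                      out_dir = "psfd_run")
res$summary          # AUC / sensitivity / specificity / balanced accuracy
                     # per arm x feature set, with bootstrap CIs
```

which writes feature tables (CSV), evaluation reports (JSON) and
feature-change tables under `psfd_run/`.

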