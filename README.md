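# strokemri

Multimodal quantitative MRI analysis of experimental mouse stroke, built as
a reusable R package plus an analysis workflow. It targets the standard
imaging readouts of the transient middle-cerebral-artery-occlusion (tMCAO)
model — the filament stroke model in which strain background (C57Bl/6 vs
Sv/129) is a recurring suspected confounder — and is aimed at researchers
who need the full chain from raw multi-contrast acquisitions to group
statistics:

* **T2 relaxometry** — voxel-wise monoexponential fit
  `S(TE) = S0·exp(−TE/T2)` over the first 20 echoes of a CPMG train
  (log-linear initialization + damped Gauss–Newton);
* **T1 mapping** — magnitude inversion recovery `|S0(1 − B·e^{−TI/T1})|`;
* **ADC mapping** — two-point diffusion estimator
  `ADC = −(1/b)·ln(SI_b/SI_0)` with b = 800 s/mm² (coefficient −0.00125);
* **CBF mapping** — continuous arterial spin labeling, single-compartment
  quantification
  `CBF = 6000·(λ/T1[s])·(S_ctl − S_lbl)/(2α·S_ctl)` mL/100 g/min, with
  α = 0.7 and λ = 0.95 mL/g;
* **spatial normalisation** — brain extraction, rigid 6-DOF registration to
  a common template (masked normalized cross-correlation, multi-resolution
  derivative-free search), atlas-space resampling;
* **lesion analysis** — infarct segmentation by a strict 34 ms T2 threshold,
  ventricular-CSF removal, emulated manual volumetry, infarct/hemisphere
  volume ratios;
* **group statistics** — within-group infarct probability maps, ROI
  summaries (mean ± SEM), and the exact matched-pairs Wilcoxon signed-rank
  test (full 2ⁿ sign-assignment null distribution for n ≤ 12).

Because the animal images behind this design are not publicly deposited,
the package includes a first-class digital mouse-brain phantom
(`build_template()`, `make_lesion()`, `synthesize_subject()`,
`synthesize_cohort()`) that simulates the study's acquisition geometry
(64×64 matrix, 2.5 cm FOV, 13 coronal slices, 32-echo CPMG, b ∈ {0, 800},
CASL pairs, IR series) with Rician noise and known ground truth, so every
stage is validated by parameter recovery. See the methods vignette
(`vignettes/phantom-stroke-analysis.Rmd`) for the models, defaults and
design choices.

## Worked example

Simulate one 24 h post-occlusion subject at SNR 40, map T2, segment the
infarct and quantify it:

```r
library(strokemri)

template <- build_template(acq_geometry())
lesion <- lesion_ground_truth(template, cortical_fraction_2h = 0.53,
                              cortical_fraction_24h = 0.92, rng_seed = 7)
raw <- synthesize_subject(template, lesion = lesion_mask(lesion, "24h"),
                          noise_sigma = 25, seed = 7)

t2 <- fit_t2_map(raw$echo_train, raw$echo_times_ms,
                 mask = raw$brain_mask_native, geometry = template$geometry)
t2
#> <quant_map> [ms] 64x64x13 grid, 14128 valid voxels, median 44.79

seg <- remove_csf(segment_infarct_t2(t2, 34, raw$brain_mask_native),
                  template_mask(template, "ventricle"))
vr <- volume_ratio(seg, template)
sprintf("infarct/hemisphere ratio: %d / %d = %.3f",
        vr$lesion_voxels, vr$hemisphere_voxels, vr$ratio)
#> "infarct/hemisphere ratio: 2778 / 7064 = 0.393"
```

The fitted T2 map has a healthy-tissue median of ~45 ms; the 34 ms
threshold plus CSF removal recovers the simulated lesion, which fills 39%
of the ipsilateral hemisphere — the order of magnitude expected one day
after a 60 min occlusion. Perfusion and diffusion in the cortical MCA
territory:

```r
adc <- compute_adc_map(raw$dwi_b0, raw$dwi_bpos, mask = raw$brain_mask_native)
t1  <- fit_t1_map(raw$ir_series, raw$inversion_times_ms,
                  mask = raw$brain_mask_native, geometry = template$geometry)
cbf <- compute_cbf_map(raw$casl_control, raw$casl_label, t1,
                       mask = raw$brain_mask_native)
ctx <- template_mask(template, "cortex_mca")
sprintf("cortical ROI: CBF %.1f mL/100g/min, ADC %.3g mm^2/s",
        roi_mean_map(cbf, ctx), roi_mean_map(adc, ctx))
#> "cortical ROI: CBF 29.6 mL/100g/min, ADC 0.00059 mm^2/s"
```

both deep in the ischemic range (severe hypoperfusion, restricted
diffusion). Paired group comparison of, say, volume ratios:

```r
wilcoxon_signed_rank_exact(c(0.10, 0.43, 0.38, 0.45),
                           c(0.06, 0.37, 0.42, 0.40))
#> <wilcoxon_result> W = 9, n_eff = 4, p = 0.25 (exact_enumeration)
```

## The analysis workflow

`analysis/` holds the numbered drivers for the full two-strain study
(8 + 8 subjects, 2 h and 24 h):

1. `01_simulate_cohorts.R` — simulate both cohorts and write NIfTI volumes
   plus ground-truth sidecars under `results/cohort/`;
2. `02_analyze_cohorts.R` — run the complete pipeline (`run_pipeline()`):
   mapping, step-wise registration, segmentation, probability maps,
   volumetry, ROI statistics and Wilcoxon comparisons; writes
   `results/pipeline/results.json`, CSV tables and report figures;
3. `03_recovery_calibration.R` — Monte-Carlo check that recovered group
   means fall within 2 SEM of their generating values.

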