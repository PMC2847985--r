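---
title: "Quantitative MRI analysis of experimental mouse stroke on a phantom cohort"
author: "strokemri"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative MRI analysis of experimental mouse stroke on a phantom cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis

`strokemri` re-implements, as a tested pipeline, the multimodal quantitative
MRI analysis used to compare stroke outcome between C57Bl/6 and Sv/129 mice
in the transient middle-cerebral-artery-occlusion (tMCAO) model: voxel-wise
parameter mapping (T2, T1, ADC, CBF), rigid registration of every subject to
a common atlas, threshold-based infarct segmentation, within-group infarct
probability maps, infarct/hemisphere volumetry, and exact matched-pairs
Wilcoxon statistics. Because the original animal images are not publicly
available, the package ships a digital mouse-brain phantom that generates
multi-subject, multi-timepoint raw acquisitions with known ground truth;
every stage of the analysis is validated by parameter recovery on that
phantom.

## Quantitative mapping models

* **T2 relaxometry.** The CPMG echo train is fitted voxel-wise with the
  monoexponential `S(TE) = S0 exp(-TE/T2)`, using exactly the first 20 of the
  32 echoes (echo spacing 4.2 ms, so TE = 4.2k ms). The log-linear closed
  form initializes a damped Gauss–Newton refinement on the untransformed
  signal (relative tolerance 1e-8, at most 100 iterations), vectorised across
  voxels. Voxels with non-positive signal or a failed fit are flagged
  invalid, never imputed.
* **T1 mapping.** A three-parameter magnitude inversion-recovery model
  `|S0 (1 - B exp(-TI/T1))|`. Polarity of the pre-null samples is restored by
  testing the two sign patterns around the magnitude minimum and keeping the
  lower-residual fit.
* **ADC.** The two-point estimator `ADC = -(1/b) ln(S_b / S_0)` with
  b = 800 s/mm², i.e. a coefficient of exactly −0.00125 mm²/s per unit log
  signal ratio.
* **CBF.** The single-compartment arterial-spin-labeling quantification
  `CBF = 6000 (λ / T1[s]) (S_ctl − S_lbl) / (2 α S_ctl)` in mL/100 g/min,
  with inversion efficiency α = 0.7 and brain–blood partition coefficient
  λ = 0.95 mL/g. No transit-time or slab-geometry corrections are applied:
  the study that this pipeline mirrors states only α and λ, so the plain
  single-compartment form is the faithful choice. T1 defaults to the fitted
  map; a fixed literature value can be configured instead (the original
  acquisition protocol never describes its T1 measurement).

Negative ADC or CBF estimates (possible under noise) are retained unclamped
and flagged, so that group means remain unbiased; clamping is left to the
reporting layer.

## Segmentation and group statistics

Infarct is segmented in atlas space by a fixed T2 threshold of 34 ms,
applied strictly (`T2 < 34`); voxels exactly at the threshold are healthy.
The strictness and the direction are configurable: the phantom assigns
infarcted tissue T2 = 30 ms and healthy tissue 45 ms, so infarct lies
*below* the threshold. At very high field, healthy parenchymal T2 is short
and ischemic edema *prolongs* T2, so an analysis of real data at such fields
may need `below = FALSE`; the phantom's convention follows the pipeline
contract and is self-consistent end-to-end. Intraventricular CSF is removed
after thresholding using the atlas ventricle labels, emulating the one
manual step of the original analysis.

Within-group probability maps are voxel-wise means of the subjects' binary
masks, so every value is a multiple of 1/n. A ROI's infarct probability is
the group mean of the per-subject percentage of ROI voxels infarcted, which
is algebraically identical to the ROI average of the probability map — in
particular a ROI that every subject infarcts completely reports exactly
100 ± 0. Whole-brain volumetry emulates manual delineation by returning the
phantom's ground-truth lesion (optionally degraded by a configurable rater
error) and reports infarct/hemisphere volume ratios against the ipsilateral
(right) hemisphere.

Between-strain comparisons use the exact matched-pairs Wilcoxon signed-rank
test: zero differences are discarded (the classical convention; Pratt
handling is available), |d| is ranked with mid-ranks, and for n ≤ 12 the
two-sided p-value is exact, computed from the full null distribution of W
over all 2ⁿ sign assignments conditional on the observed ranks
(`p = min(1, 2 min(P(W ≤ w), P(W ≥ w))`). The distribution is built by
shift-convolution over the doubled ranks, which is mathematically identical
to explicit enumeration; the test suite verifies bit-for-bit agreement with
a brute-force enumeration oracle and with `wilcox.test(exact = TRUE)` on
tie-free data. Larger samples fall back to the tie-corrected normal
approximation with continuity correction. Animals are paired across strains
by cohort order; the pairing rule is configurable because the original
matching criterion is not recoverable.

## Registration

Six degrees of freedom are interpreted as rigid (3 rotations + 3
translations) — the conventional reading of a "6-DOF affine" alignment.
Registration maximises masked normalized cross-correlation with a
derivative-free search: a 2× in-plane downsampled level is explored from a
small multi-start stencil (±2°, ±1 voxel per axis) and refined by
Nelder–Mead, then polished at full resolution. Both images are pre-smoothed
with an anisotropic Gaussian (σ = 2 voxels in-plane, 1 through-plane);
besides the usual capture-range benefit, the smoothing suppresses trilinear
interpolation ripple, which otherwise biases the NCC optimum by a few tenths
of a degree at this slice thickness. Subjects are registered on their b = 0
(proton-density) image against the template's proton-density reference, and
step-wise: 2 h to 24 h within subject, then 24 h to template, composed.
Transforms rotate about the volume centre, map moving-world (mm) to
fixed-world, and serialize to JSON.

Resampling is trilinear for intensity maps and nearest-neighbour for labels
and masks; out-of-field voxels take a declared fill value and are excluded
from downstream masks. Two refinements matter for correctness:

* quantitative maps are warped with *validity-weighted* (normalized)
  interpolation, so invalid voxels do not bleed zeros into valid neighbours;
* the T2 map that feeds threshold segmentation is warped nearest-neighbour.
  Trilinear mixing of 30 ms infarct and 45 ms healthy tissue would place the
  34 ms contour at a 73%-infarct partial-volume weight rather than at the
  true boundary, systematically eroding the mask.

## The phantom

The template is a deterministic geometric brain on the acquisition grid
(64 × 64 in-plane over a 2.5 × 2.5 cm field of view, 13 coronal slices at
1 mm spacing): an ellipsoidal brain split into hemispheres, a lateral
cortical band standing for the centre of the MCA territory, a deep
subcortical ROI (caudoputamen/pyramidal tract analogue), and paired
ventricles. Both ROIs lie wholly in the right (ipsilateral) hemisphere.

Proton density is an *analytic* field: a tissue/CSF level with a smooth
sigmoidal edge profile (~1 voxel wide, emulating partial-volume roll-off)
multiplied by a fixed low-frequency sinusoidal texture. Displaced subjects
are synthesized by evaluating this function at the exact transformed
coordinates — like acquiring a rotated head — rather than by resampling a
stored volume, which would blur the moving image relative to the template
and bias registration. Tissue parameter classes (T2, T1, ADC, CBF) are
looked up nearest-neighbour at the transformed coordinates for the same
reason: a real acquisition does not interpolate relaxation times across the
brain edge.

Lesions always cover the full subcortical ROI (subcortical infarction
completes early, reflecting the poor collateral supply of the basal
ganglia) plus a connected fraction of the cortical ROI grown geodesically
from an origin near the subcortex. The growth ordering is deterministic
given the seed, so a larger fraction strictly nests a smaller one and 2 h
lesions are guaranteed subsets of 24 h lesions. Default cortical fractions
are 0.607 (C57Bl/6) and 0.533 (Sv/129) at 2 h and 0.951 / 0.921 at 24 h,
chosen so the group summaries land at the observed cortical infarct
probabilities; a consequence of the "subcortex always complete" contract is
that the phantom's 2 h subcortical probability is 100%, whereas real 2 h
subcortical infarction is partial — a deliberate simplification.

Default tissue levels: healthy T2 45 ms, T1 2200 ms, ADC 8.0 × 10⁻⁴ mm²/s,
CBF 90 mL/100 g/min, S0 1000; CSF 200 ms / 4300 ms / 3.0 × 10⁻³ / ~0 / 1200;
infarct T2 30 ms with strain-, timepoint- and ROI-specific ADC and CBF
levels (e.g. cortical CBF 34.1 falling to 22.3 mL/100 g/min in Sv/129 mice,
ADC 7.8 falling to 5.8 × 10⁻⁴ mm²/s). Noise is Rician — the magnitude of a
complex Gaussian — with σ = 25 against S0 = 1000 (SNR 40) by default; a
Gaussian option exists for analytic checks. In background the magnitude mean
converges to σ√(π/2), which the tests verify.

Between-subject variability is normal, truncated at zero, with CV 15% on
the functional parameters (CBF, ADC, S0) and 5% on the relaxometric ones
(T2, T1). The T2 multiplier is additionally truncated so that every
subject's infarct T2 stays below 34 − 2 ms and healthy T2 above 34 + 2 ms:
without that margin (which the tissue model owes the threshold
segmentation), occasional subjects would cross the fixed 34 ms cut and the
contract "subcortical infarction segments completely" would fail for
reasons unrelated to the pipeline. Head pose is uniform within ±5° per
rotation axis and ±2 voxels per translation axis. One master seed
deterministically derives all per-subject, per-timepoint and per-sequence
seeds through a multiplicative counter hash, so cohorts reproduce
bit-for-bit and a sequence's noise does not depend on which other sequences
are simulated.

What the phantom does **not** emulate: k-space or Bloch simulation, partial
volume beyond the S0 edge profile, B0/B1 inhomogeneity, motion, perfusion
kinetics beyond the single-compartment model (the CASL pair is constructed
by inverting the same quantification formula, which is what makes the
noise-free round trip exact and is also why CBF recovery does not probe
model error), and the CASL slab geometry (treated as sharing the common
grid; the original sequence excited a single thick slab). Passing tests
therefore demonstrate correctness of the estimators, the geometry and the
statistics — not robustness to acquisition physics the phantom omits.

## Numerical and design choices

* CPMG timing `4.2/2000 ms` is read as echo spacing 4.2 ms with TR 2000 ms
  (matching the DWI notation where 2000 ms is unambiguously TR).
* Strict `<` at the threshold makes the boundary case deterministic; a
  uniform 34 ms map segments empty.
* No connected-component filtering after thresholding (none is described for
  the original analysis); available as an optional flag, default off. No
  edema/swelling correction.
* "Hemisphere" in the volume ratio is the ipsilateral (right) hemisphere.
* Registration fill value is 0 with validity-mask exclusion, so atlas-edge
  voxels never contaminate ROI statistics.
* Fits run at 64 × 64 × 13 scale as closed-form/vectorised operations; the
  suite's Monte-Carlo calibrations use 100 repetitions of 8-subject cohorts,
  1000-replicate single-voxel noise studies, and 100-seed property tests —
  sizes at which the binomial uncertainty of a 95% coverage check is about
  ±2 percentage points, which should be kept in mind when reading the
  recovery results.
* Nominal coverage of a `|recovered − generating| ≤ 2 SEM` check is 95.4%
  under the generative model; the acceptance bar of 95% leaves slack of less
  than half a point, so that check is expected to sit close to its
  threshold.

## Limitations

The phantom's geometry is schematic (ellipsoids, not anatomy) and its
contrast direction at the segmentation threshold is a convention, not a
measurement. Registration accuracy figures (≲0.2° and ≲0.02 voxel
translations on noise-free phantoms) reflect matched analytic contrast and
should be read as an upper bound on what the implementation achieves on real
data. The Wilcoxon pairing across independent strains follows cohort order,
as in the mirrored study design, but such pairing is statistically arbitrary
for truly independent groups.
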