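---
title: "Models and design of the perfcon perfusion-concordance pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design of the perfcon perfusion-concordance pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perfcon)
```

## What the package computes

`perfcon` reproduces, on fully synthetic data with known ground truth, the
analysis chain used to ask how well arterial spin labeling (ASL) MRI agrees
with ¹⁵O-water PET — the reference standard — at detecting regional
cerebral hypoperfusion in single patients:

1. a digital brain phantom with tissue-dependent cerebral blood flow
   (CBF), arterial transit times (ATT) and focal hypoperfused lesions;
2. forward simulation of the raw measurements: dynamic ¹⁵O-water PET,
   phase-contrast (PC) vessel flow, single-delay (SD) pCASL, and Hadamard
   time-encoded ("free lunch", FL/TE) pCASL;
3. CBF quantification per modality — a whole-brain-calibrated PET method
   that needs no arterial sampling, and single-compartment ASL kinetic
   modeling with and without transit-time fitting;
4. single-case hypoperfusion mapping against a small control cohort with
   the Crawford–Howell modified t-test and a sphere-equivalent
   cluster-extent rule;
5. concordance metrics between modalities: ROI-level
   sensitivity/specificity, the overlapping/adjacent/isolated voxel
   partition, Jaccard similarity, cluster-volume change, ROI regression
   and Bland–Altman agreement.

Because every simulated subject carries its ground truth, each stage can
be validated by recovery rather than by eyeballing.

## The phantom and what it does (not) emulate

`build_phantom()` uses an ellipsoidal-shell geometry: a cortical GM shell
(CBF 60 ml/100 g/min by default) around a WM core (20 ml/100 g/min) with
a central zero-flow CSF cavity. Lesions are spheres that reduce CBF by a
stated fraction. ATT grows smoothly from the centre outward within
700–1700 ms — distal territories fill later — with a small seeded smooth
modulation so ATT is not a pure function of radius. M0 is
tissue-dependent (GM 850, WM 700, CSF 1000 a.u.).

The default grid is 64 × 64 × 48 voxels at 2 mm isotropic: small enough
for minute-scale runs while matching the voxel volume under which a
10 mm sphere equals 65 voxels. Tests use 4–8 mm grids; the physics does
not depend on the grid.

Deliberately **not** modeled: anatomy-derived geometry, partial-volume
mixing at tissue borders (labels are crisp), scanner point-spread
functions, k-space/readout effects, motion, and PET reconstruction
(simulated frames are decay-corrected activities, as reconstructed
frames are). Passing tests therefore demonstrate correctness of the
numerical chain under the stated kinetic models, not robustness to the
full messiness of acquired data. Measurement noise is Gaussian: per ASL
volume with a fixed SD, and per PET frame with SD scaled by
1/sqrt(frame duration) to mimic count statistics without a full Poisson
reconstruction model.

## Dynamic PET and whole-brain-calibrated quantification

Each voxel follows one-tissue-compartment kinetics,
dC/dt = (f/100)·Ca(t) − (f/(100λ))·C(t), with λ = 0.9 ml/g the water
partition coefficient and Ca a gamma-variate bolus input. The ODE is
solved with an exact exponential-integrator recursion on a 0.02 s grid —
once per unique CBF value, since phantom CBF is piecewise constant — and
frame values are trapezoid averages over each frame of the 5-minute,
37-frame schedule (3 s × 20, 5 s × 6, 10 s × 6, 30 s × 5).

Quantification (`pmrflow_cbf()`) avoids arterial sampling by calibrating
with the whole-brain CBF from PC MRI
(`f_wb = 100 Σ v̄ₖAₖ / brain mass`):

$$f_i = \frac{\int_0^T C_i\,dt}{\tfrac{1}{f_{wb}}\int_0^T C_{wb}\,dt
 + \tfrac{1}{\lambda}\int_0^T\!\!\int_0^t C_{wb}
 - \tfrac{1}{\lambda}\int_0^T\!\!\int_0^t C_i}$$

with T = 300 s. All integrals are trapezoidal on frame midpoints with a
(0, 0) anchor — frames start at injection, so activity is zero
beforehand; the integrator is a numerical choice, made explicit because
the method itself does not prescribe one. Time is handled in minutes and
flows in ml/g/min internally, returning ml/100 g/min. Voxels with a
non-positive denominator are marked invalid, not clipped, so they can be
excluded from control-group statistics instead of biasing them.

**A property worth knowing.** If a voxel's curve equals the whole-brain
curve, the double-integral terms cancel and the method returns `f_wb`
exactly — the package tests this at machine precision, and a
uniform-CBF phantom is recovered exactly for the same reason. But the
calibration estimates the cumulative input-function integral from the
whole-brain curve *assuming that curve follows one-tissue kinetics at
the mass-weighted mean flow*. A brain that mixes kinetically distinct
tissues violates this: writing p, q for the GM/WM volume fractions and
DD for the double time integrals, the input-integral estimate is offset
by (1/λ)(p − p f_G/(p f_G + q f_W))(DD_G − DD_W), which is negative
whenever GM flow exceeds WM flow. The denominator is then too small and
CBF is overestimated everywhere — on the default phantom GM comes back
at ≈ 76 instead of 60 and WM at ≈ 22.4 instead of 20 (values confirmed
against an independent fine-grid closed-form computation). The effect
survives any physiological input function we tried (narrow bolus,
recirculation plateau, constant infusion). Two practical consequences:
the recovered GM/WM contrast (≈ 3.4) exceeds the true ratio (3.0),
consistent with the elevated PET-vs-ASL contrast reported in clinical
comparisons of these methods; and voxelwise absolute accuracy on
strongly bimodal phantoms is limited by the method, not by this
implementation. Relative and case-control analyses are largely
insensitive to it, since it acts approximately as a smooth gain field
shared by patients and controls.

## ASL signal model and quantification

`buxton_signal()` implements the single-compartment pCASL solution with
times in ms: zero before the label arrives (t < ATT); a saturating
rise 2·α·M0b·(f/6000)·T1'·e^(−ATT/T1b)(1 − e^(−(t−ATT)/T1')) during
labeling; exponential decay afterwards. The apparent T1 defaults to the
blood T1 (T1' = T1b), with a tissue-T1 mode available; the labeled pool
is arterial blood, so the simulators pass M0b = M0/λ. Constants follow
consensus recommendations — λ = 0.9 ml/g, T1b = 1650 ms, labeling
efficiency α = 0.85 — and the net background-suppression attenuation is
0.83 (two inversion pulses at ≈ 0.91 efficiency each). All are
config-overridable.

SD-pCASL (LD 1800 ms, PLD 2000 ms, 16 pairs) is quantified by the exact
closed-form inversion
CBF = 6000·λ·ΔM·e^(PLD/T1b) / (2·α_eff·T1b·M0·(1 − e^(−LD/T1b))).
Under T1' = T1b the transit-time factors cancel whenever ATT ≤ PLD, so
noiseless recovery is exact there — which is why the closed form, rather
than a one-parameter fit, is used: with a single delay they are
equivalent under the model, and the closed form is exactly invertible
for testing.

Time-encoded ASL uses the Sylvester Hadamard matrix with the all-ones
column dropped; +1 marks a labeled sub-bolus and the first acquired
volume labels all of them. Decoding is the signed combination
ΔMₖ = −(2/N)Σᵢ hᵢₖ·volᵢ, exactly linear and exact for arbitrary
signals. Effective timing of sub-bolus k is its own duration as LD and
final PLD plus all later durations as PLD; the default N = 8 scheme
(2000 ms free-lunch bolus + 6 × 250 ms, final PLD 200 ms) yields the
PLD ladder 1700, 1450, 1200, 950, 700, 450, 200 ms.

The (CBF, ATT) fit replaces Bayesian spatially regularized inference
with independent voxelwise bounded least squares — deterministic,
prior-free, and testable; the concordance layer is agnostic to the
fitting engine. Since the model is linear in CBF at fixed ATT, the fit
is a dense ATT-grid search (5 ms default step, bounds [0, max PLD +
max LD]) with closed-form CBF per candidate, keeping CBF ≥ 0. Grid
candidates whose predicted signal is identically zero (label arriving
after every readout) are dropped. All-zero voxels return CBF 0, ATT at
the lower bound, flagged low-confidence. At ATT exactly equal to the
largest effective PLD only the free-lunch sub-bolus retains signal and
the pair (CBF, ATT) is unidentifiable — the practical ATT range should
stay inside the sampled ladder. The free-lunch sub-bolus is included in
the fit by default (`include_first = FALSE` to exclude it), since the
data contain no motion outliers that would argue for discarding it.

Maps are smoothed (6 mm PET, 8 mm ASL defaults) with a separable
Gaussian restricted to and renormalized within the validity mask, then
intensity-normalized so the brain mean equals the PC-MRI whole-brain
CBF; relative (rCBF) maps divide by a reference-region mean (whole
brain by default, any mask — e.g. the atlas's posterior reference
sector — otherwise).

## Single-case statistics

With a small control group (n ≈ 13), treating the control mean and SD
as population values inflates false positives. The Crawford–Howell
statistic t = (x − mean)/(sd·√((n+1)/n)) with n − 1 degrees of freedom
is exactly t-distributed under the null, so thresholding at the
one-sided t quantile holds the voxelwise type-I error at α — the
package verifies 0.045–0.055 empirically at α = 0.05 over 10⁵ null
draws, and shows the naive z threshold exceeds it. Only the lower tail
is tested (hypoperfusion). Voxels invalid in any contributing map are
excluded rather than imputed, and zero-SD voxels are invalid.

Clusters are connected components at 26-connectivity (configurable;
"connected" alone does not fix a neighbourhood). The extent threshold
is the voxel equivalent of a 10 mm sphere — floor((π/6)d³/v) with v the
voxel volume, 65 voxels at 2 mm — and clusters *at* the threshold are
retained ("greater than a sphere" read as at-least-its-volume; the
strict reading is one `min_voxels` unit away). An ROI is called
hypoperfused when its largest in-ROI component reaches the threshold;
a cluster straddling ROIs contributes only its in-ROI voxels to each
(whole-cluster attribution is available as a switch).

In the overlap partition, test-only components touching any overlap
voxel under the connectivity are "adjacent", the rest "isolated"; an
adjacency radius is otherwise undefined, and one connectivity step is
the minimal choice. Group-level ROI comparisons default to Welch's
unequal-variance test, because patients and controls are independent
subjects; a paired mode exists for same-subject cross-modality
comparisons.

## Problem sizes and determinism

Tests and the worked examples run on 16³–32³ grids with 4–5 controls,
which keeps the full suite under a minute while exercising every code
path; the default 64 × 64 × 48 grid runs a complete cohort in a few
minutes. Everything is deterministic given the configuration seed:
per-subject seeds are derived arithmetically from it, noiseless
simulators are bit-reproducible, and `run_pipeline()` writes a
provenance JSON sufficient to reproduce any output.

## Known limitations

- Whole-brain-calibrated PET CBF carries the heterogeneity
  overestimation derived above, and additionally ignores the blood
  volume signal contribution — both are properties of the method being
  reproduced, not corrections applied.
- The ASL model has no macrovascular (arterial blood volume)
  compartment and no partial-volume correction; ATT beyond the sampled
  PLD ladder is unidentifiable by design.
- Crisp phantom labels make lesion boundaries sharper than biology;
  sensitivity estimates on synthetic lesions are therefore optimistic.
- No multiple-comparison correction beyond the cluster-extent rule is
  applied, mirroring the single-case analysis being emulated.

## A worked miniature

```{r}
cfg <- default_config(
  grid = list(shape = c(32L, 32L, 24L), voxel_size = c(4, 4, 4)),
  n_controls = 4,
  patients = list(list(id = "p1",
                       lesions = list(list(center = c(64, 100, 48),
                                           radius = 16,
                                           cbf_reduction = 0.6)))),
  modalities = c("pet", "asl_sd"))
res <- run_pipeline(cfg, scales = "absolute")
res$concordance[, c("patient", "modality", "sensitivity", "specificity",
                    "overlap_pct", "jaccard")]
```

In the noiseless limit both modalities flag exactly the lesioned
region: ROI sensitivity and specificity are 1 and every ASL voxel lies
inside the PET mask (overlap 100%). Adding ASL noise degrades the
Jaccard index monotonically while the ROI-level calls stay robust much
longer — the same qualitative pattern the concordance metrics show on
patient data.
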