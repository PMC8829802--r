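# perfcon

Simulation and concordance analysis of PET and ASL cerebral perfusion
imaging.

## The problem

¹⁵O-water PET is the reference standard for imaging cerebral blood flow
(CBF), but it needs a cyclotron next door. Pseudo-continuous arterial
spin labeling (pCASL) MRI measures perfusion without tracer or
radiation, which makes it attractive for detecting the regional
hypoperfusion that accompanies neurodegeneration (e.g. frontotemporal
dementia), where single-patient maps — not group averages — are what a
clinic needs. The question is how far the two modalities' single-subject
hypoperfusion maps agree.

`perfcon` implements that comparison as a reusable, fully testable
pipeline on synthetic data with known ground truth, for methods
researchers in perfusion imaging: a digital brain phantom; forward
simulation of dynamic water PET, phase-contrast (PC) vessel flow,
single-delay pCASL, and Hadamard time-encoded ("free lunch") pCASL;
quantification to CBF per modality; single-case statistics; and the
full set of concordance metrics.

## The methods at its core

**Whole-brain-calibrated PET CBF** (no arterial sampling). With
C_i(t) a voxel's time-activity curve, C_wb(t) the whole-brain curve,
λ = 0.9 ml/g the water partition coefficient, T = 5 min, and f_wb the
whole-brain CBF from PC MRI (`f_wb = 100 Σ v̄ₖ Aₖ / brain mass`):

    f_i = ∫₀ᵀ C_i dt / [ (1/f_wb)∫₀ᵀ C_wb dt
                         + (1/λ)∫₀ᵀ∫₀ᵗ C_wb − (1/λ)∫₀ᵀ∫₀ᵗ C_i ]

**ASL kinetic modeling.** The single-compartment pCASL solution
ΔM(t) = 2 α M0b (f/6000) T1' e^(−ATT/T1b)(1 − e^(−(t−ATT)/T1')) (rise;
exponential decay after labeling ends), inverted in closed form for
single-delay data and fitted jointly over (CBF, ATT) for the N = 8
time-encoded scheme, whose sub-boli (2000 ms free-lunch + 6 × 250 ms,
final PLD 200 ms) decode by signed Hadamard combination into
perfusion-weighted images at effective PLDs 1700 … 200 ms.

**Single-case statistics.** Each patient map is compared voxelwise to a
small control cohort with the Crawford–Howell modified t-test,
t = (x − x̄)/(s·√((n+1)/n)), df = n − 1, thresholded one-sided at
α = 0.05, with a cluster-extent rule equal to a 10 mm sphere
(65 voxels at 2 mm).

**Concordance.** ROI-level sensitivity/specificity against the PET
masks, the overlapping/adjacent/isolated voxel partition, Jaccard
similarity, cluster-volume change, ROI-mean regression and
Bland–Altman limits of agreement.

## A worked example

```r
library(perfcon)

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
                    "overlap_pct", "jaccard", "volume_change_pct")]
#>   patient modality sensitivity specificity overlap_pct   jaccard
#> 1      p1   asl_sd           1           1         100 0.9275362
#>   volume_change_pct
#> 1          7.246377
```

One patient with a 16 mm, 60%-reduction lesion is simulated alongside
four controls and analysed noiselessly in both modalities. Every ROI
the PET mask flags is also flagged by ASL and vice versa (sensitivity
= specificity = 1); all ASL-detected voxels fall inside the PET mask
(overlap 100%, nothing adjacent or isolated); the masks' Jaccard index
is 0.93 because the PET mask is ~7% larger (`volume_change_pct`).
Individual stages are exposed directly — e.g.

```r
hadamard_timing(hadamard_scheme())$effective_plds
#> [1] 1700 1450 1200  950  700  450  200
type1_error_sim(n_controls = 13, n_patients_null = 1e5, alpha = 0.05,
                seed = 123)
#> [1] 0.04943
```

— the free-lunch PLD ladder of the N = 8 encoding, and the empirical
false-positive rate of the Crawford–Howell procedure sitting at its
nominal 5% for a 13-subject control group.

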