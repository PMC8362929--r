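---
title: "Methods: perfusion heterogeneity and hypothermic electrophysiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: perfusion heterogeneity and hypothermic electrophysiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(coolwedge)
```

This vignette is the package's own account of its models and the choices
behind them: what is computed, under which assumptions, with which
defaults, and what the synthetic data can and cannot tell you.

## The scientific setting

Cooling the dialysate used in peritoneal dialysis (from 37 °C to 32 °C)
has been proposed as a cardioprotective intervention. Two quantitative
questions sit behind it:

1. Does cooling change the *spatial heterogeneity* of myocardial blood
   flow (a microcirculation marker), even when mean flow is unchanged?
2. What would cooling do to ventricular electrophysiology — the action
   potential, the ECG, and the persistence of re-entrant arrhythmia — in
   a myocardium stressed by the "ischemia-like" state of dialysis?

The package implements the computational half of such a study: a
relative-dispersion fractal analysis of 3D flow maps, a human
ventricular cell model with temperature and ischemia parameterizations,
a monodomain transmural-wedge simulator with a pseudo-ECG, paired
nonparametric statistics, and a synthetic-data generator that emulates
the study design (7 subjects × normothermic/hypothermic visits ×
rest/adenosine-stress scans).

## Fractal dimension by relative dispersion

For a masked 3D flow map, voxels are aggregated into in-plane blocks of
`m` voxels (doubling alternately along X and Y: 1×1, 2×1, 2×2, 4×2, …),
each 5 mm slice kept separate. At every aggregation factor the relative
dispersion `RD(m) = SD/mean` of the retained block means is computed,
and the fractal dimension is

$$\mathrm{FD} = 1 - \text{slope of } \log RD \text{ vs } \log m .$$

Two limits anchor the scale: a perfectly uniform map has no dispersion
at any scale and is reported as FD = 1 (homogeneity convention,
triggered when RD at the base scale is below 1e−12); spatially
uncorrelated flow gives `RD ∝ m^{-1/2}`, hence FD = 1.5, the complete
heterogeneity reference. The aggregation variable is the *number of
voxels per block* — with per-axis factors instead, uncorrelated noise
would scale with slope −1 and the 1.5 reference would not hold.

Numerical choices:

* **In-plane-only aggregation.** With 0.5 × 0.5 × 5 mm voxels, isotropic
  3D blocks would be geometrically absurd at small factors. Slices are
  aggregated independently and pooled.
* **Block retention.** A block enters the statistic only if ≥ 50% of its
  voxels are masked (mean over masked voxels only). This prevents the
  thin rim of the ventricular shell from biasing the dispersion.
* **Scale range.** Aggregation stops when fewer than 20 retained blocks
  remain; the log–log fit requires ≥ 3 scales, otherwise an error names
  the smallest admissible grid. Estimates outside [1, 1.5] are reported
  with an `in_range = FALSE` flag, never clamped.

## Synthetic perfusion maps

No generative model of myocardial flow is given in the source study;
the generator is a documented stand-in. Each slice receives an isotropic
power-law (spectral-synthesis) texture `P(k) ∝ k^{-β}`, slices share a
common component (`slice_cor`, default 0.6) so neighbouring slices
correlate, and `noise_fraction` of the voxel variance may be replaced by
spatially uncorrelated noise. The field is scaled to `mean_bf` with a
relative dispersion of `rel_sd` (default 0.35) at voxel scale, floored
at 1 mL/min/100 g (zero flow is nonphysical and breaks RD), and
re-scaled so the masked mean lands within 1% of the target.

The map from a target FD to the spectral exponent β cannot be taken
from theory — the estimator's in-plane geometry and masking define FD
operationally here — so it was calibrated against the package's own
estimator: 10 seeds per β on a 128 × 128 × 16 grid, frozen as a lookup
table with monotone interpolation. Recovery of targets 1.1–1.4 is
within ±0.01 on that geometry (the acceptance tolerance is ±0.05).

The left-ventricle mask is a half-ellipsoid shell (outer semi-axes
40 × 40 × 80 mm, 10 mm wall) voxelized on the standard grid — roughly
16 slices of 5 mm, apex down. It mimics the volume and rim geometry of
a segmented LV, not any patient anatomy.

The paired cohort generator encodes the emulated study conditions as
defaults: 7 subjects; rest median flow 133 mL/min/100 g with
between-subject lognormal CV 0.12 (reproducing the printed 116–175
range); stress = 271/133 ≈ 2.04 × rest; hypothermic rest flow
125/133 ≈ 0.94 × normothermic (the reported non-significant drop); FD
1.30 at normothermic rest with a −14% shift under cooling, plus a
further −6% rest→stress drop under cooling only. Subject-level FD
deviations (SD 0.015) plus estimator noise give paired differences an
effect-to-noise ratio large enough that the n = 7 exact Wilcoxon test
detects the −14% shift in ≥ 80% of seeds — that is the implicit claim
of a p = 0.03 result at n = 7, made explicit.

What passing tests on these maps do *not* show: real CT perfusion maps
have scanner noise, deconvolution artefacts, partial-volume rims and
anatomical FD gradients none of which are modelled; the generator
demonstrates estimator correctness, not clinical validity.

## The ventricular cell model

The cardiomyocyte is the 2006 human ventricular formulation of the ten
Tusscher–Panfilov family (epicardial, M, endocardial variants differing
in I~to~ and I~Ks~ density), integrated with Rush–Larsen exponential
updates for the 12 gates and forward Euler elsewhere at dt = 0.02 ms
(halving dt moves APD90 by < 1 ms). The compiled implementation is
cross-checked in the test suite against an independently coded pure-R
reference of the same published equations; the two agree to ~10^-14 mV
over a paced beat.

**Therapeutic hypothermia** is standard Q10 scaling, with the actual
absolute temperature also entering the Nernst potentials:

| parameter | default | meaning |
|---|---|---|
| `q10_gates` | 3.0 | gate-rate slowing on cooling (×0.58 at 32 °C) |
| `q10_conductance` | 1.3 | conductance/pump reduction (×0.88 at 32 °C) |
| `q10_katp` | 3.0 | ATP-sensitive K⁺ conductance suppression |

At 32 °C the control epicardial APD90 moves from ~307 ms to ~470 ms with
a reduced upstroke — prolongation and slowed conduction, the canonical
cooling phenotype.

**The dialysis "ischemic" condition** is the acute phase-1a triad,
linear in `ischemia_severity`: extracellular K⁺ 5.4 → `ko_max` mM;
ATP-sensitive K⁺ current activated up to `f_atp_max` = 0.5% open
fraction (Shaw–Rudy-type formulation, `g_katp` = 2 mS/µF at full
activation); 25% block of fast Na⁺ and L-type Ca²⁺ conductances. At
severity 1 and 37 °C this yields the canonical ischemic AP: APD90
~180 ms, resting potential elevated to ~−76 mV, upstroke velocity
reduced ~2.7-fold, amplitude preserved.

Two defaults deserve explanation because they were genuinely open:

* `ko_max = 8` mM rather than a harsher 9 mM: combined with the Na⁺
  block, 9 mM pushes tissue conduction to ~8 cm/s — the edge of
  conduction failure — where the activation delay across the wall
  (>150 ms) swamps every repolarization gradient and temperature can no
  longer reshape the T wave. At 8 mM the full ischemic phenotype is
  intact with physiologic (if slow) conduction.
* `q10_katp = 3`: cooling strongly suppresses the ischemic K⁺ leak.
  This is the mechanism by which hypothermia pulls the ischemic AP and
  ECG back toward control in this model; it is exposed as configuration
  like every other Q10.

The exact cellular parameterization used by the source study is not
publicly available; all six knobs above are configuration, chosen once
to reproduce the qualitative cellular and ECG phenotypes the study
reports, and never fitted to data.

## The monodomain wedge and its pseudo-ECG

The tissue model is a monodomain reaction–diffusion slab, default
15 mm (transmural) × 20 × 20 mm, isotropic diffusivity
1.54 × 10⁻³ cm²/ms, no-flux boundaries, solved by operator splitting
(ionic reaction per node, 7-point finite-difference Laplacian with
face-averaged diffusivity; the explicit stability bound on dt is
checked and violations are rejected with the admissible bound). The
default node spacing is 0.25 mm; all desk-scale analyses here use the
2D mode (one node deep) at 0.5 mm, where halving dx changes QRS and QT
by under 5%. Conduction velocity on a control strand is ~57 cm/s,
inside the 40–80 cm/s physiological band.

Cell types are assigned by transmural position with layer fractions
endo:M:epi = 0.10:0.30:0.60 — a thin stimulated endocardial rim, a
subendocardial M band, and a thick epicardial layer. This choice is
deliberate and matters: electrotonic coupling makes repolarization
largely follow the activation sequence, and with a mid-wall M band the
steep endocardial repolarization limb dominates the far-field dipole
and inverts the control T wave. Placing the M band subendocardially
puts the slowest-repolarizing tissue far from the electrode and yields
the upright control T expected of a lateral-lead-like electrode. The
fractions are configuration for exactly this reason.

The electrode sits on the transmural axis 30 mm beyond the epicardial
face. The pseudo-ECG is the standard unipolar dipole-source sum

$$\phi_e(t) = -\sum_i D_i \, \nabla V_m^{(i)} \cdot \nabla\!\left(\tfrac1r_i\right)\, \Delta V,$$

in arbitrary units (the study reports morphology, not calibrated
millivolts); it is identically zero for quiescent tissue, falls off
with electrode distance, and is verified in the tests against an
independent plain-loop dipole sum on stored Vm fields.

Condition runs pace one endocardial beat after per-cell-type
single-cell pre-pacing: `control` = (severity 0, 37 °C), `NT_PD` =
(severity 1, 37 °C), `TH_PD` = (severity 1, 32 °C). Under control the
T is upright; under NT_PD activation slows, repolarization follows
activation, and the T inverts with a shortened ST and QT; under TH_PD
the QRS widens further (cold conduction), QT and ST prolong, and the
suppressed ischemic K⁺ leak re-creates enough repolarization gradient
that the T inversion becomes milder than at 37 °C.

### ECG measurement rules

On noiseless simulated traces: isoelectric line = median of the 20 ms
pre-stimulus window; QRS onset = stimulus time; J point = first return
of |φ| below 5% of the QRS peak after the last QRS extremum; T wave =
largest-|area| deflection after J; T end by the tangent method
(steepest post-peak slope extrapolated to baseline); T onset = first
crossing of 25% of the T extremum, ST = J to T onset. The 25% onset
threshold (not 5%) is deliberate: severely ischemic tissue starts
repolarizing during activation, there is no isoelectric ST segment, and
a 5% rule degenerates to ST ≡ 0 for every ischemic trace, erasing the
very contrast being measured. All thresholds are arguments.

## Re-entry assay

The S1–S2 assay runs on an all-M 2D sheet (the tests use
40.5 × 40.5 mm at 0.75 mm spacing and dt = 0.05 ms — coarse but stable,
chosen because persistence is a comparative, not metric, readout)
carrying a structural heterogeneity field: severities derived from the
low-flow quantile of a synthetic perfusion map (rising linearly from 0
at the quantile threshold to 1 at the lowest-flow voxel), mapped onto
the sheet over a baseline severity of 0.4 — the dialysis myocardium is
modelled as globally stressed with severe low-flow cores, which is
also what makes the substrate arrhythmogenic at desk scale: without
the baseline, the long refractory period of unstressed tissue blocks
re-invasion after a single rotation on a sheet this small. Severity
also scales local diffusivity, down to the configured floor (0.2 here)
at severity 1.

One conditioning S1 at the sheet edge is followed by a cross-field S2
over one quadrant at each coupling interval; re-entry is scored when
any node activates ≥ 3 times after S2, and persistence is the time
from S2 to the last activation (capped). Coupling intervals are
scanned near each condition's own effective refractory period —
roughly the longest coupled-tissue APD plus electrotonic prolongation
(≈ 350–370 ms normothermic, ≈ 480–560 ms cooled on this substrate);
probing the cooled sheet at the normothermic window would only find
refractory block and prove nothing. The S1 phase is simulated once per
condition/seed and each coupling interval resumes from the stored
state. On this substrate the normothermic ischemic sheet supports
induced re-entrant activity that persists several rotations before
self-terminating, while under cooling the prolonged wavelength (longer
APD, suppressed K⁺ leak) closes the vulnerable window across its whole
scanned range — the model's account of cooling's antiarrhythmic
effect. The flow-to-severity coupling is an invented, documented
construction, not a measured dose–response.

## Paired statistics

NT/TH comparisons use the Wilcoxon signed-rank test exactly as the
study's analysis plan describes: summaries as median (min–max), zero
differences dropped (Wilcoxon's rule), midranks for ties, two-sided p
by complete enumeration of all 2ⁿ sign assignments for n ≤ 15 (a
tie-corrected normal approximation with continuity correction above),
and no multiplicity correction. At n = 7 the attainable two-sided
p-values are quantized: 2/128 ≈ 0.0156 when all seven differences share
a sign, 0.03125 with a single smallest-rank discordance — which is the
arithmetic behind a printed "p = 0.03" at n = 7. Effect sizes are
reported as the percent change of the TH median relative to NT.

## Problem sizes used

Analyses in the tests and acceptance script run at desk scale, chosen
as the smallest sizes at which each estimate is stable: FD reference
cases on 128 × 128 × 16 box grids (10 seeds); cohort checks on
48 × 48 × 6 grids and pipelines on the full 168 × 168 × 16 shell grid;
wedge morphology on the 2D 15 × 20 mm slab at dx = 0.5 mm; re-entry on
a 30 × 30 mm sheet with 5 heterogeneity seeds. The 3D wedge mode and
the 0.25 mm default spacing are available for full-scale runs.

## Known limitations

* The generator's power-law texture is stationary within a slice; real
  perfusion heterogeneity is anisotropic and non-stationary.
* The TH/PD cellular parameterization is a literature-informed
  configuration, not a fit; absolute APD/QT values should be read as
  model output, not prediction.
* The monodomain slab has no fibre anisotropy, no torso, and a single
  electrode; only waveform morphology and within-model contrasts are
  meaningful.
* The re-entry assay's vulnerable window is scanned at 10 ms
  resolution on a small sheet; persistence values are comparative, not
  absolute.
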