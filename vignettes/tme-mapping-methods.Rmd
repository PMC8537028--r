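---
title: "Methods: voxelwise tumor microenvironment mapping"
author: "tmemap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxelwise tumor microenvironment mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmemap)
```

This vignette documents the models, the numerical choices and the design
decisions behind `tmemap`, in the spirit of a methods section: what is
computed, under which assumptions, with which defaults, and what the
synthetic validation does and does not demonstrate.

## 1. The physiological model chain

### Diffusion and relaxometry

The ADC map uses the two-point estimator `ADC = -ln(S_b/S_0)/b` with
b = 1000 s/mm². Negative estimates caused by noise are clamped to zero
and flagged; non-positive signals make a voxel invalid (`NA`), and
invalid voxels propagate through every later stage rather than being
silently zeroed.

R2\* and R2 come from voxelwise monoexponential fits
`S(TE) = S0 exp(-R·TE)` to the 8-echo gradient-echo (TE 5–40 ms) and
spin-echo (TE 13–104 ms) series. The default estimator is log-linear
least squares weighted by the squared signal: the weighting restores
near maximum-likelihood behavior of the log-transformed problem while
keeping the estimator deterministic, closed-form and fast; a
Levenberg–Marquardt refinement exists for the bolus fits where the model
is nonlinear in its parameters. Two corrections mirror standard qBOLD
practice in simplified form:

* **Through-slice background gradients** superimpose a sinc-shaped
  attenuation on the gradient-echo decay. `correctBackgroundGradient()`
  divides each echo by `|sinc(γ G Δz TE/2)|` given a gradient estimate;
  with no estimate it is a warned no-op. A full background-field
  correction from measured field maps is intentionally out of scope.
* **Stimulated echoes** bias the first echo of a multi-echo spin-echo
  train; the default (`drop_first_se_echo`) discards that echo before
  fitting, which removes the dominant bias term. A full
  extended-phase-graph treatment is out of scope; the surrogate is
  declared, not claimed equivalent.

### DSC perfusion

Signal curves convert to relaxation-rate changes as
`ΔR2(t) = -ln(S(t)/S̄_base)/TE` over a pre-bolus baseline (10 of 60
volumes by default). The first-pass window is found once on the global
(brain-mean) curve — from the bolus foot to the first local minimum
after the peak — because bolus timing is a property of the injection,
not of the voxel; each voxel keeps its own tail end so long-transit
voxels are not truncated. Within that window every voxel's first pass is
fitted by a gamma-variate `K(t-t0)^α exp(-(t-t0)/β)`: a deterministic
log-linearised fit over a grid of arrival times supplies the start
values, and a Levenberg–Marquardt polish (default on) refines them on
the original scale. The fitted curve replaces the raw one downstream,
which is what removes recirculation. A curve whose smoothed first-pass
peak does not exceed `detection_k = 5` times the smoothed baseline noise
SD is flagged invalid — the guard against fitting pure noise.

The AIF is selected automatically: candidate voxels are scored by high
peak, early arrival and narrow width (`peak/(width × arrival)`), gated
at the median tissue peak and arrival, and the ten best raw curves are
averaged; ties break on the lowest linear voxel index so selection is
deterministic. A measured AIF can be supplied through the config
instead.

Absolute quantification follows the integral and deconvolution routes:

* `CBV = k_H · ∫ΔR2,tissue / ∫ΔR2,AIF` with
  `k_H = (1-Hct_art)/(1-Hct_art·0.85)` (arterial hematocrit 0.42, the
  0.85 small-vessel correction shared with the qBOLD constant). The
  tissue integral uses the raw samples over the first-pass window plus
  the fitted tail beyond it: under noise the direct integral has
  substantially lower variance than the fitted-curve integral, while the
  fitted tail keeps long-MTT voxels unbiased.
* `CBF = (k_H/ρ) · max R(t)` from block-circulant (delay-insensitive)
  truncated-SVD deconvolution of the fitted tissue curve against the
  fitted AIF, ρ = 1.04 g/mL, converted to mL/100 g/min. Singular values
  below 10% of the maximum are discarded. The classical 20% cut is
  tuned for deconvolving raw noisy curves; here the inputs are fitted
  (already denoised) curves, and on 60-point sampling the heavier
  truncation only adds low-pass bias to the residue peak, so the
  default is 0.10 (configurable).

Discretisation makes the recovered flow MTT-dependent (the residue is
effectively area-sampled over TR = 1.74 s, so short-MTT voxels read
low); this is a property of all sampled DSC deconvolution, and the
phantom presets anticipate it (section 3).

Contrast extravasation is handled by a Boxerman-style linear correction:
the voxel curve is regressed on the non-enhancing whole-brain reference
curve and its running integral, and the integral (leakage) component is
subtracted. The stage is exercised and tested in isolation but disabled
in the default phantom pipeline: the default phantom contains no
extravasation term, and regressing non-leaky curves on a reference of
different hemodynamic shape only adds variance. The pre-bolus role of
the spin-echo injection in the acquisition protocol is represented by
this correction stage alone; no explicit pre-bolus model is built.

### Oxygen metabolism and vascular architecture

The qBOLD chain is
`OEF = (R2* - R2)/(k·CBV)` with `k = (4/3)π·γ·Δχ·Hct·B0 ≈ 316.8 s⁻¹`
at 3 T, `CMRO2 = C_a·CBF·OEF`, and
`PO2 = p50·(2/OEF - 1)^{1/h} - CMRO2/L`. All constants live in
`physioConstants()`: γ = 2.67502×10⁸ rad/s/T, Δχ = 0.264 ppm,
Hct = 0.42×0.85, C_a = 8.68 µmol O₂/mL blood, p50 = 27 mmHg, h = 2.7,
L = 4.4 µmol/(100 g·min·mmHg). Two unit conventions deserve note:
C_a and L are carried in micromolar units so that CMRO₂ lands in the
µmol/100 g/min range of the classification table, and OEF is stored as
a fraction with classification applied to 100·OEF. PO₂ below zero is
retained numerically (such voxels are simply hypoxic); clamping at zero
is available for rendered maps (`po2_clamp_zero`).

The vascular hysteresis loop (VHL) is the closed curve of
`ΔR2,GE` against `(ΔR2,SE)^{3/2}` over the first pass, traversed in
acquisition order, negative SE values clamped before the 3/2 power. MTI
is minus the shoelace signed area, so a clockwise loop (x right, y up)
is positive. Positive MTI is labeled arteriole-dominated and negative
capillary/venule-dominated (strong neovascularization); the sign-to-
biology mapping is a label, not a computation. In the pipeline the loop
is evaluated from the two fitted gamma-variates on a 128-point fine
grid, which makes the area independent of the acquisition sampling.

`Q_max = max[ΔR2,GE]/max[(ΔR2,SE)^{3/2}]` uses the spin-echo curve in
the denominator, consistent with the VHL axes; a literal variant with
the gradient-echo curve in both numerator and denominator is available
behind `qmax_literal` for sensitivity checks but contradicts the axis
definitions and is off by default. MVD and VSI are computed literally
from the semi-empirical formulas (b = 1.6781, R̄ = 3 µm); their
dimensional analysis is not exact, which is a property of the published
formulas, so no cross-consistency between MVD and VSI is asserted
anywhere.

## 2. Classification

Each ROI voxel is classified on (CMRO₂, OEF%, MTI, MVD, PO₂) by the
fixed criteria table, with strict inequalities at every written bound
and a closed normoxic band (10 and 60 mmHg are both normoxic). The
precedence order necrosis → hypoxia-without-NV → hypoxia-with-NV →
glycolysis → OxPhos resolves the genuine overlap between the necrosis
and hypoxia-without-NV cells (e.g. CMRO₂ 100, OEF 80 satisfies both);
necrosis wins because its OEF criterion is the stricter one. Voxels
matching no rule stay in an explicit unclassified class (label 0) — no
nearest-class fallback is invented — and `auditRules()` quantifies both
the gaps (e.g. CMRO₂ < 80 with OEF 50–75 matches nothing) and the
overlaps on a dense biomarker grid. Necrosis ignores PO₂ entirely:
with near-absent perfusion the PO₂ estimate there is unreliable by
construction.

Before classification the five input maps are median-filtered in-plane
(3×3) strictly within the ROI. This is conventional edge-preserving
noise reduction for voxelwise parameter maps: on constant regions the
filter is exact, it never mixes tumor with brain across the ROI
boundary, and isolated failed-fit voxels are filled from their
neighborhood. PO₂ is then recomputed from the filtered OEF and CMRO₂ so
the five maps stay mutually consistent. Likewise, the raw series are
smoothed in-plane (3×3, mask-aware, never across the ROI boundary)
before any fitting — the standard resolution-for-noise trade of
DSC/qBOLD processing. Both steps are configurable and independent of
the classification rules themselves; label-level spatial
regularization, by contrast, is deliberately not performed.

## 3. The synthetic phantom

`generatePhantom()` forward-simulates every raw series from known
ground truth on a 32×32×8 grid of 1.8×1.8×4 mm voxels (60 dynamic
volumes at TR 1.74 s, GE/SE echo times 22/33 ms, 8-echo GRE and SE
trains, a b = 0/1000 DWI pair): monoexponential echo decays, diffusion
attenuation, and first-pass bolus curves built as AIF ⊛ exponential
residue with area CBV/CBF. The AIF is a gamma-variate (t₀ = 22 s,
α = 3, β = 1.5 s, peak 180 s⁻¹) giving a ~13 s first pass; a corner
block of arterial voxels carries it at three-fold baseline signal so
automatic AIF selection has a physical target. The GE/SE hysteresis is
induced by a pure time lag plus amplitude scale — the simplest
mechanism that yields a closed loop of controllable signed area — with
the SE amplitude set to hit a prescribed Q_max; a biophysical
vessel-caliber simulation is a non-goal. Rician noise of SD
`S0/SNR` is applied to signal magnitudes only, never to derived
quantities, under a single seed.

The tumor is a sphere partitioned into contiguous angular wedges with
prescribed volume shares (default 40/20/20/10/10), ordered
glycolysis–OxPhos–hypoxia-NV–necrosis–hypoxia-no-NV so that adjacent
compartments are biologically and biomarker-wise compatible, as nested
tumor zones are. The per-compartment presets
(`defaultCompartmentPresets()`) were designed by construction: the
required postcondition is that a noiseless forward simulation pushed
through the full inverse pipeline lands strictly inside the intended
classification cell, which forces the ground-truth flow values to
anticipate the known MTT-dependent discretisation loss of sampled
deconvolution, and places each preset away from cell edges so that the
voxelwise noise at the default test SNR of 50 does not tip interior
voxels across a bound. Blood volumes of 5–8%, flows of 8–110
mL/100 g/min, OEF of 5–95% and ADC of 0.9–1.4×10⁻³ mm²/s span the
ranges reported for enhancing tumor tissue. SNR defaults are chosen for
testability: the per-voxel, per-timepoint noise of real acquisitions is
not characterized in a way this phantom could copy.

What passing the phantom tests shows: the implementation inverts its
own forward models to numerical precision; the full chain recovers a
known five-compartment composition within a few percentage points under
realistic noise; the classification honors its criteria exactly. What
it does not show: accuracy on real data, where the forward models
themselves (static dephasing, AIF partial volume, leakage, motion,
partial-volume mixtures at compartment interfaces) are approximations —
the phantom shares those model families with the pipeline by design.

## 4. Statistics

Per-subject compartment percentages are voxel counts over the whole
enhancing ROI (voxel volume is constant within an acquisition);
unclassified voxels stay in the denominator by default, with a
classified-only denominator behind a flag because published compartment
tables typically sum to ~100% without a residual class. Vital (active)
tumor is glycolysis + OxPhos; total hypoxia is the sum of the two
hypoxia classes.

Group comparisons run a median-centered Brown–Forsythe/Levene gate at
α = 0.05 (centering and α configurable; the robust median variant is
the default): homogeneous variances lead to one-way ANOVA with Tukey
HSD, heterogeneous variances to Welch's ANOVA with Games-Howell
pairwise tests. Welch ANOVA and Tukey delegate to the standard R
implementations; Games-Howell is implemented from its defining formulas
(per-pair Welch–Satterthwaite degrees of freedom, `√2·|t|` referred to
the studentized range distribution) because no installed package
provides it — only the studentized-range CDF comes from base R. No
multiple-testing correction is applied beyond the post hoc procedures
themselves. The type-I error of the full gate-then-test procedure is
verified by simulation to stay near the nominal level.

## 5. Numerical and reproducibility notes

* Voxel indexing is 0-based in world-coordinate conventions; world
  coordinates come only from the NIfTI affine; no reorientation is
  performed (all series are co-registered by construction).
* Invalid voxels carry `NA` everywhere; classification maps reserve
  label 0 for unclassified/invalid.
* Every stochastic step (phantom noise, simulations) draws from a
  single configured seed; identical config + seed reproduces every
  output byte for byte, which the test suite asserts on the summary
  files.
* The config is one YAML-serializable document; every constant of the
  physiological models and every classification threshold defaults to
  its published value and is overridable; each run writes a JSON
  provenance record of the values actually used, including the MTI sign
  convention.
* Test problem sizes: unit tests run on 8³–16³ grids in seconds; the
  noiseless single-compartment recovery experiments use 16×16×4
  phantoms; the mixed-composition recovery experiment uses a 40×40×10
  grid (tumor radius ~14 voxels, ~5200 ROI voxels) so that every
  compartment, including the 10%-share ones, is several voxels thicker
  than the reach of the smoothing and median kernels — on smaller grids
  the thin compartments consist almost entirely of boundary voxels and
  the experiment measures kernel reach, not recovery. The full suite
  stays in the minutes range on one CPU.

## 6. Known limitations

The qBOLD OEF is a static-dephasing-regime estimate, vessel-size
weighted and blind to intravascular signal; susceptibility sources
other than deoxyhemoglobin bias it, and in near-avascular tissue the
whole chain rests on a small CBV denominator — the reason necrosis
classification ignores PO₂. MVD and VSI are semi-empirical and carry
inexact dimensions. The leakage correction is first-order linear. The
phantom does not simulate motion, partial-volume mixing beyond the
smoothing kernel, B0/B1 inhomogeneity, or contrast-agent recirculation;
conclusions about those effects cannot be drawn from it. The hysteresis
lag mechanism produces loops of controllable area but does not model
vessel-caliber biophysics.
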