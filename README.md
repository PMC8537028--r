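# tmemap — tumor microenvironment mapping from physiological MRI

Contrast-enhancing brain tumors (glioblastoma, metastases, CNS lymphoma,
meningioma) are metabolically heterogeneous: parts of the tumor run on
aerobic glycolysis (the Warburg effect), parts on mitochondrial oxidative
phosphorylation, and parts are hypoxic or frankly necrotic, with or
without active neovascularization. `tmemap` implements a voxelwise,
multiparametric MRI analysis that maps these five tissue states from a
single physiological MRI session, for researchers in neuro-oncology
imaging who want a fully scriptable, testable implementation of the
method.

## The method

From co-registered acquisitions the package computes, per voxel:

- **ADC** from a b = 0 / b = 1000 s/mm² DWI pair:
  `ADC = -ln(S_b/S_0)/b`;
- **R2\*** and **R2** by weighted log-linear monoexponential fits to
  multi-echo gradient-echo and spin-echo series
  (`S(TE) = S_0 e^{-R·TE}`);
- **CBV** and **CBF** from gradient-echo dynamic susceptibility contrast
  (DSC) data: signal → ΔR2 conversion, gamma-variate first-pass fitting,
  automatic arterial-input-function selection, and block-circulant
  truncated-SVD deconvolution;
- **OEF** (oxygen extraction fraction) via the quantitative BOLD model
  `OEF = (R2* - R2) / ((4/3)·π·γ·Δχ·Hct·B0 · CBV)`;
- **CMRO₂** via Fick's principle `CMRO2 = C_a · CBF · OEF`;
- **PO₂** by inverting the Hill model of hemoglobin–O₂ binding:
  `PO2 = p50·(2/OEF - 1)^{1/h} - CMRO2/L`;
- **MTI** (microvessel type indicator): the signed area of the vascular
  hysteresis loop traced by ΔR2,GE versus (ΔR2,SE)^{3/2} during bolus
  passage (clockwise positive, arteriole-dominated; counterclockwise
  negative, capillary/venule-dominated — the signature of
  neovascularization);
- **MVD** and **VSI** (microvessel density and vessel size index), the
  semi-empirical vessel-architecture measures
  `MVD = Q_max^b (CBV/(2⁴π²·ADC·R̄⁴))^{1/3}` and
  `VSI = (CBV·ADC·b³/(2π·Q_max³))^{1/2}` with
  `Q_max = max[ΔR2,GE]/max[(ΔR2,SE)^{3/2}]`.

Each ROI voxel is then classified into one of five tumor
microenvironment (TME) compartments — aerobic **glycolysis** (blue),
**OxPhos** (green), **necrosis** (black), **hypoxia with** (yellow) and
**without** (red) **neovascularization** — by fixed criteria on CMRO₂,
OEF, MTI, MVD and the PO₂ bands (hypoxia < 10 mmHg, normoxia
10–60 mmHg, high oxygen > 60 mmHg). Compartment percentages per tumor
and the derived vital-tumor (glycolysis + OxPhos) and total-hypoxia
aggregates feed group comparisons across tumor entities with a Levene
gate, one-way/Welch ANOVA, and Tukey or Games-Howell post hoc tests.

Because no patient data ship with the method, the package includes a
synthetic digital phantom (`generatePhantom()`) that forward-simulates
every raw series from known ground truth, so the entire chain is
verifiable end to end.

## Worked example

```r
library(tmemap)

# a 32x32x8 digital tumor phantom: 40% glycolysis, 20% OxPhos,
# 20% necrosis, 10% hypoxia with NV, 10% hypoxia without NV, at SNR 50
spec <- phantomSpec(snr = 50, seed = 7)
ph   <- generatePhantom(spec)
res  <- runPipeline(ph$bundle, defaultConfig(), out_dir = "phantom_out")
res$summary
```

```
CompartmentSummary over 2648 ROI voxels
  glycolysis      36.48 %
  oxphos          22.92 %
  necrosis        15.41 %
  hypoxia_nv       6.99 %
  hypoxia_nonv     5.40 %
  unclassified    12.80 %
  vital_tumor     59.40 %  (derived)
  active_tumor    59.40 %  (derived)
  total_hypoxia   12.39 %  (derived)
```

The percentages recover the prescribed 40/20/20/10/10 composition to
within a few points at this noise level; `phantom_out/` holds every
biomarker map as NIfTI, the TME label map with its color legend, the
OEF–CMRO₂ scatter table, the AIF, and a JSON provenance record of all
constants used. Group-level statistics use the same interface as the
per-subject summaries:

```r
cmp <- compareGroups(cohort_table, "total_hypoxia")
cmp$method    # "welch_games_howell" when variances are unequal
cmp$pairwise  # Games-Howell pairwise p-values
```

A command-line front end (`inst/cli/tmemap`) exposes `simulate`, `fit`,
`classify`, `stats` and `run` subcommands over the same functions.

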