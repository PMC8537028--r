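Package: tmemap
Title: Tumor Microenvironment Mapping from Physiological MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Voxelwise mapping of metabolic tumor microenvironment (TME)
    compartments in contrast-enhancing brain tumors from physiological MRI.
    Computes biomarker maps of diffusion (ADC), perfusion (CBV, CBF from
    dual-echo dynamic susceptibility contrast MRI), transverse relaxation
    (R2*, R2), oxygen metabolism (OEF, CMRO2, PO2 via the quantitative BOLD
    model), and vascular architecture (microvessel density, vessel size
    index, and the microvessel type indicator from the vascular hysteresis
    loop), then fuses them into a five-class TME map (aerobic glycolysis,
    oxidative phosphorylation, necrosis, hypoxia with and without
    neovascularization). Includes a synthetic digital phantom with known
    ground truth for end-to-end validation, per-ROI compartment summaries,
    and heteroscedastic group comparisons (Welch ANOVA with Games-Howell
    post hoc tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    yaml,
    jsonlite,
    car,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
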