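# Pipeline configuration: physiological constants, classification rules
# and processing options, all overridable but defaulting to the published
# literature values.

#' Physiological and physical constants of the oxygen-metabolism and
#' vascular-architecture models
#'
#' All literature constants used by [computeOef()], [computeCmro2()],
#' [computePo2()], [computeMvd()] and [computeVsi()] in one audited place.
#'
#' @param b0_t static field strength in tesla.
#' @return named list:
#' \describe{
#'   \item{gamma}{proton gyromagnetic ratio, 2.67502e8 rad/s/T}
#'   \item{delta_chi}{susceptibility difference between fully deoxygenated
#'     and fully oxygenated hemoglobin, 0.264e-6}
#'   \item{hct}{microvascular hematocrit 0.42 x 0.85 (systemic hematocrit
#'     times a small-vessel correction factor)}
#'   \item{b0_t}{field strength (T)}
#'   \item{ca}{arterial blood oxygen content, 8.68 umol O2/mL blood}
#'   \item{p50_mmhg}{hemoglobin half-saturation tension, 27 mmHg}
#'   \item{hill_h}{Hill coefficient of O2-hemoglobin binding, 2.7}
#'   \item{l_conduct}{tissue oxygen conductivity, 4.4 umol/(100g min mmHg)}
#'   \item{mean_radius_mm}{mean vessel lumen radius, 3.0e-3 mm}
#'   \item{b_mvd}{numerical exponent of the microvessel-density model, 1.6781}
#'   \item{hct_art, hct_small_factor}{arterial hematocrit and its
#'     small-vessel scaling, used for the DSC absolute-scaling factor}
#'   \item{rho_brain}{brain tissue density, 1.04 g/mL}
#' }
#' @export
physioConstants <- function(b0_t = 3.0) {
  list(
    gamma = 2.67502e8,
    delta_chi = 0.264e-6,
    hct = 0.42 * 0.85,
    b0_t = b0_t,
    ca = 8.68,
    p50_mmhg = 27,
    hill_h = 2.7,
    l_conduct = 4.4,
    mean_radius_mm = 3.0e-3,
    b_mvd = 1.6781,
    hct_art = 0.42,
    hct_small_factor = 0.85,
    rho_brain = 1.04
  )
}

#' The qBOLD susceptibility scaling factor k
#'
#' `k = (4/3) pi gamma delta_chi Hct B0`, the constant that converts
#' `CBV * OEF` into the reversible relaxation-rate difference R2* - R2.
#' About 316.8 1/s at 3 T with the default constants.
#'
#' @param c constants list from [physioConstants()].
#' @return k in 1/s.
#' @export
qboldK <- function(c = physioConstants()) {
  (4 / 3) * pi * c$gamma * c$delta_chi * c$hct * c$b0_t
}

#' Hematocrit/density scaling for absolute CBV and CBF
#'
#' `k_H = (1 - Hct_art) / (1 - Hct_art * small_vessel_factor)` converts the
#' tissue-to-arterial concentration integral ratio to a blood-volume
#' fraction; brain density converts per-mL to per-100g flow.
#'
#' @param c constants list from [physioConstants()].
#' @return named list with `k_h` (dimensionless) and `rho` (g/mL).
#' @export
dscScaling <- function(c = physioConstants()) {
  list(k_h = (1 - c$hct_art) / (1 - c$hct_art * c$hct_small_factor),
       rho = c$rho_brain)
}

#' Classification rules for the five TME compartments
#'
#' One row per class, in precedence order (first match wins):
#' necrosis, hypoxia without neovascularization (NV), hypoxia with NV,
#' glycolysis, OxPhos. All range comparisons are strict; the normoxic
#' PO2 band 10-60 mmHg is closed at both ends. Necrosis ignores PO2
#' (very low perfusion or avascularity would bias its estimate).
#'
#' Bounds (CMRO2 in umol/100g/min, OEF in percent, MTI in s^-5/2,
#' MVD in mm^-2, PO2 band): necrosis CMRO2 < 130, OEF > 75, |MTI| < 5,
#' MVD < 250; hypoxia-no-NV CMRO2 80-150, OEF > 50, |MTI| < 5, MVD < 250,
#' hypoxic; hypoxia-with-NV CMRO2 > 150, OEF < 50, |MTI| > 5, MVD > 250,
#' hypoxic; glycolysis CMRO2 < 150, OEF < 20, |MTI| > 5, MVD > 250,
#' hyperoxic; OxPhos CMRO2 > 70, OEF < 50, |MTI| > 5, MVD > 250, normoxic.
#'
#' @return data.frame of per-class predicate parameters with attributes
#'   `mti_limit` (5.0 s^-5/2) and `mvd_limit` (250 mm^-2).
#' @export
classificationRules <- function() {
  r <- data.frame(
    class  = c("necrosis", "hypoxia_nonv", "hypoxia_nv", "glycolysis", "oxphos"),
    label  = c(3L, 5L, 4L, 1L, 2L),
    cmro2_lo = c(-Inf, 80, 150, -Inf, 70),
    cmro2_hi = c(130, 150, Inf, 150, Inf),
    oef_lo   = c(75, 50, -Inf, -Inf, -Inf),
    oef_hi   = c(Inf, Inf, 50, 20, 50),
    nv       = c(FALSE, FALSE, TRUE, TRUE, TRUE),
    po2_band = c(NA, "hypoxic", "hypoxic", "hyperoxic", "normoxic"),
    stringsAsFactors = FALSE)
  attr(r, "mti_limit") <- 5.0
  attr(r, "mvd_limit") <- 250
  r
}

#' Default pipeline configuration
#'
#' A single plain-list document (YAML/JSON serializable) collecting every
#' tunable of the pipeline. All physical constants and classification
#' thresholds default to the published values; processing options are
#' declared here so a run is fully reproducible from its config and seed.
#'
#' @param seed random seed used for every stochastic step.
#' @param b0_t field strength (T).
#' @return nested named list; see the methods vignette for the meaning,
#'   units and rationale of each entry.
#' @export
defaultConfig <- function(seed = 1L, b0_t = 3.0) {
  list(
    seed = as.integer(seed),
    b0_t = b0_t,
    constants = physioConstants(b0_t),
    thresholds = list(
      mti_limit = 5.0,      # s^-5/2
      mvd_limit = 250,      # mm^-2
      po2_hypoxia = 10,     # mmHg
      po2_hyperoxia = 60    # mmHg
    ),
    adc = list(b_value = 1000),      # s/mm^2
    preprocess = list(
      spatial_smooth = TRUE,         # mask-aware in-plane smoothing of the
      smooth_size = 3                # raw series before any fitting
    ),
    relaxometry = list(
      weighted = TRUE,               # squared-signal weighted log-linear fit
      drop_first_se_echo = TRUE      # stimulated-echo surrogate correction
    ),
    dsc = list(
      svd_threshold = 0.10,          # TSVD cut, fraction of max singular value
      detection_k = 5,               # first-pass peak must exceed k x noise SD
      detection_smooth = 5,          # moving-average window for detection
      aif_mode = "auto",             # "auto" or "supplied"
      aif_top_n = 10,
      leakage_correction = FALSE,    # Boxerman-style correction stage
      qmax_literal = FALSE,          # use GE curve in the Q_max denominator
      refine_fits = TRUE             # nonlinear polish of gamma-variate fits
    ),
    classification = list(
      median_filter = TRUE,          # ROI-restricted median filter of the
      median_filter_size = 3         # five classification input maps
    ),
    po2_clamp_zero = FALSE,          # clamp PO2 at 0 before classification
    out_dir = NULL
  )
}

#' Read / write a pipeline config as YAML
#'
#' Values present in the file override the defaults; everything else keeps
#' its default, so a config file only needs to list deviations.
#'
#' @param path YAML file.
#' @return for `readConfig`, a full config list.
#' @export
readConfig <- function(path) {
  usr <- yaml::read_yaml(path)
  utils::modifyList(defaultConfig(), usr)
}

#' @rdname readConfig
#' @param config config list.
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
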