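# Synthetic digital phantom: forward-simulates every raw acquisition the
# pipeline consumes (multi-echo GRE/SE, GE/SE-DSC, DWI pair, ROI mask)
# from a ground-truth description of tumor compartments.

#' Default arterial input function of the phantom
#'
#' A gamma-variate first pass `K (t-t0)^alpha exp(-(t-t0)/beta)` with a
#' ~13 s first-pass width, matched to a 60-point series at TR 1.74 s. The
#' amplitude is set by the peak arterial dR2 (default 180 1/s), a
#' true-concentration scale at which tissue curves reach realistic peaks.
#'
#' @param t0 arrival time (s).
#' @param alpha,beta shape and scale.
#' @param peak peak arterial dR2 (1/s).
#' @return named list of gamma-variate parameters.
#' @export
defaultAif <- function(t0 = 22, alpha = 3, beta = 1.5, peak = 180) {
  list(k = peak / ((alpha * beta)^alpha * exp(-alpha)),
       t0 = t0, alpha = alpha, beta = beta)
}

#' Ground-truth parameter presets per TME compartment
#'
#' For each of the five compartments (plus normal-appearing white matter,
#' `"wm"`) a parameter set whose noiseless forward simulation, pushed
#' through the inverse pipeline, yields biomarker values strictly inside
#' that compartment's classification cell. The presets were designed by
#' construction against the noiseless pipeline (deconvolution recovers
#' flow with a known MTT-dependent discretisation loss on the 60-point
#' grid, which the flow values anticipate) and are fixed.
#'
#' Columns: `cbv` (fraction), `cbf` (mL/100g/min), `oef` (fraction),
#' `adc` (mm^2/s), `r2` (1/s), `r2star` (1/s, = r2 + OEF k CBV),
#' `lag_s` (GE/SE hysteresis lag, s), `loop_direction` (+1 clockwise /
#' -1 counterclockwise), `qmax_target` (s^1/2).
#'
#' @param c constants from [physioConstants()].
#' @return data.frame keyed by `class`.
#' @export
defaultCompartmentPresets <- function(c = physioConstants()) {
  p <- data.frame(
    class = c("glycolysis", "oxphos", "necrosis", "hypoxia_nv",
              "hypoxia_nonv", "wm"),
    cbv   = c(0.08, 0.05, 0.05, 0.06, 0.06,  0.025),
    cbf   = c(75,   55,   8,    130,  20,    25),
    oef   = c(0.05, 0.28, 0.95, 0.40, 0.65,  0.35),
    adc   = c(1.2e-3, 1.0e-3, 1.4e-3, 0.9e-3, 1.0e-3, 0.8e-3),
    r2    = c(12,   12,   13,   12.5, 12.5,  12.5),
    lag_s = c(3.0,  3.0,  0,    3.0,  0,     0.5),
    loop_direction = c(-1, -1, 1, -1, 1, 1),
    qmax_target = c(1.2, 1.2, 0.24, 1.3, 0.24, 0.35),
    stringsAsFactors = FALSE)
  p$r2star <- p$r2 + p$oef * qboldK(c) * p$cbv
  rownames(p) <- p$class
  p
}

#' Phantom specification
#'
#' Describes grid geometry, acquisition parameters, tumor composition and
#' the noise model of a synthetic acquisition. The tumor is a sphere of
#' enhancing tissue inside a white-matter background, partitioned into TME
#' compartments by prescribed volume shares; a small corner block of
#' arterial voxels carries the pure AIF for automatic AIF selection.
#'
#' @param dim grid size (voxels), default 32 x 32 x 8.
#' @param voxel_mm voxel size, default 1.8 x 1.8 x 4 mm.
#' @param shares named volume shares of the tumor sphere over the classes
#'   `glycolysis, oxphos, necrosis, hypoxia_nv, hypoxia_nonv` (normalized
#'   internally).
#' @param tumor_radius sphere radius in voxels (in-plane); default scales
#'   with the grid.
#' @param snr signal-to-noise ratio of the tissue baseline (Rician noise on
#'   signal magnitude); `Inf` for noiseless.
#' @param noise_model `"rician"` or `"gaussian"`.
#' @param seed RNG seed for the noise draws.
#' @param n_time,tr_s dynamic series length and repetition time.
#' @param te_ge_s,te_se_s DSC echo times (s).
#' @param n_baseline pre-bolus volumes.
#' @param te_gre_s,te_mese_s multi-echo GRE and SE echo times (s).
#' @param b_value DWI b-value (s/mm^2).
#' @param s0,s0_artery baseline signal of tissue and arterial voxels.
#' @param aif AIF parameters from [defaultAif()].
#' @param presets compartment presets ([defaultCompartmentPresets()]).
#' @return list of class `phantom_spec`.
#' @export
phantomSpec <- function(dim = c(32, 32, 8), voxel_mm = c(1.8, 1.8, 4),
                        shares = c(glycolysis = 0.4, oxphos = 0.2,
                                   necrosis = 0.2, hypoxia_nv = 0.1,
                                   hypoxia_nonv = 0.1),
                        tumor_radius = 0.36 * dim[1], snr = Inf,
                        noise_model = "rician", seed = 1L,
                        n_time = 60, tr_s = 1.74,
                        te_ge_s = 0.022, te_se_s = 0.033,
                        n_baseline = 10L,
                        te_gre_s = seq(0.005, 0.040, length.out = 8),
                        te_mese_s = seq(0.013, 0.104, length.out = 8),
                        b_value = 1000, s0 = 1000, s0_artery = 3000,
                        aif = defaultAif(),
                        presets = defaultCompartmentPresets()) {
  if (snr <= 0) stop("SNR must be positive")
  stopifnot(all(names(shares) %in% presets$class))
  structure(as.list(environment()), class = "phantom_spec")
}

# voxel partition of the phantom: returns list(region = integer array with
# 0 wm, -1 artery, 1..5 tumor classes in preset label order)
.phantom_geometry <- function(spec) {
  d <- spec$dim
  reg <- array(0L, d)
  ctr <- (d + 1) / 2
  ix <- slice.index(reg, 1); iy <- slice.index(reg, 2)
  iz <- slice.index(reg, 3)
  # sphere in voxel units, z scaled by voxel anisotropy
  zs <- spec$voxel_mm[3] / spec$voxel_mm[1]
  r2 <- (ix - ctr[1])^2 + (iy - ctr[2])^2 + ((iz - ctr[3]) * zs)^2
  tumor <- which(r2 <= spec$tumor_radius^2)
  shares <- spec$shares / sum(spec$shares)
  # wedge order places biomarker-compatible compartments next to each
  # other, as in real tumors where hypoxic and necrotic zones are nested
  ord <- c("glycolysis", "oxphos", "hypoxia_nv", "necrosis", "hypoxia_nonv")
  shares <- shares[intersect(ord, names(shares))]
  cls <- names(shares)
  # contiguous angular wedges: order tumor voxels by in-plane angle around
  # the center (real compartments are spatially coherent regions)
  ang <- atan2(iy[tumor] - ctr[2], ix[tumor] - ctr[1])
  tumor <- tumor[order(ang, r2[tumor], tumor)]
  n <- length(tumor)
  cuts <- round(cumsum(shares) * n)
  from <- c(1, utils::head(cuts, -1) + 1)
  for (i in seq_along(cls)) {
    if (from[i] > cuts[i]) next
    reg[tumor[from[i]:cuts[i]]] <- match(cls[i],
      c("glycolysis", "oxphos", "necrosis", "hypoxia_nv", "hypoxia_nonv"))
  }
  # arterial block in a corner, away from the tumor
  nz <- d[3]
  reg[1:3, 1:3, 1:nz] <- -1L
  reg
}

#' Forward DSC model for one tissue compartment
#'
#' Generates the paired GE/SE first-pass curves of a voxel with blood
#' volume `cbv` and flow `cbf`: the GE curve is the AIF convolved with an
#' exponential residue (area CBV/CBF); the SE curve is an amplitude-scaled,
#' time-lagged copy of the GE curve, the simplest mechanism that opens the
#' vascular hysteresis loop with a controllable rotational direction
#' (`loop_direction = +1`: SE lags GE, clockwise loop, positive MTI). The
#' SE amplitude is set so the curve pair attains a prescribed Q_max. The
#' apparent (concentration-space) volume and flow include the hematocrit
#' and density scalings that the measuring pipeline divides back out.
#'
#' @param cbv blood-volume fraction (> 0).
#' @param cbf flow in mL/100g/min.
#' @param aif AIF parameter list ([defaultAif()]).
#' @param times_s acquisition time grid (s).
#' @param loop_direction +1 clockwise / -1 counterclockwise.
#' @param lag_s GE-SE temporal lag (s); must be smaller than the bolus
#'   width. 0 gives a degenerate (zero-area) loop.
#' @param qmax_target prescribed Q_max (sets the SE amplitude).
#' @param te_ge_s,te_se_s echo times used to derive the signal curves.
#' @param s0 baseline signal.
#' @param oversample fine-grid factor for the convolution.
#' @param c constants from [physioConstants()].
#' @return list with `ge_dr2`, `se_dr2`, `ge_signal`, `se_signal` on
#'   `times_s`, plus the fine-grid curves.
#' @export
forwardDsc <- function(cbv, cbf, aif = defaultAif(),
                       times_s = (0:59) * 1.74,
                       loop_direction = 1, lag_s = 0, qmax_target = 1,
                       te_ge_s = 0.022, te_se_s = 0.033, s0 = 1000,
                       oversample = 10, c = physioConstants()) {
  if (cbv <= 0) stop("cbv must be positive")
  sc <- dscScaling(c)
  v_app <- cbv / sc$k_h
  f_app <- cbf * sc$rho / (6000 * sc$k_h)
  mtt <- v_app / f_app
  dt <- (times_s[2] - times_s[1]) / oversample
  tf <- seq(0, max(times_s) + 10 * dt, by = dt)
  a <- gammaVariate(tf, aif$k, aif$t0, aif$alpha, aif$beta)
  r <- exp(-tf / mtt)
  ge_f <- f_app * dt * stats::convolve(a, rev(r), type = "open")[seq_along(tf)]
  # bolus width guard: full width at half maximum of the GE curve
  above <- tf[ge_f > 0.5 * max(ge_f)]
  fwhm <- if (length(above) > 1) diff(range(above)) else 0
  if (abs(lag_s) >= fwhm && lag_s != 0)
    stop("lag_s must be smaller than the bolus width (FWHM ",
         round(fwhm, 1), " s)")
  gep <- max(ge_f)
  se_scale <- gep^(-1 / 3) * qmax_target^(-2 / 3)
  # loop_direction +1: SE lags GE (clockwise VHL)
  se_f <- se_scale *
    stats::approx(tf + loop_direction * lag_s, ge_f, tf, rule = 2)$y
  ge <- stats::approx(tf, ge_f, times_s, rule = 2)$y
  se <- stats::approx(tf, se_f, times_s, rule = 2)$y
  list(ge_dr2 = ge, se_dr2 = se,
       ge_signal = s0 * exp(-ge * te_ge_s),
       se_signal = s0 * exp(-se * te_se_s),
       fine = list(t = tf, ge = ge_f, se = se_f),
       mtt = mtt, fwhm = fwhm)
}

.add_noise <- function(x, sigma, model) {
  if (sigma <= 0) return(x)
  n1 <- array(stats::rnorm(length(x), 0, sigma), dim(x))
  if (model == "gaussian") return(x + n1)
  n2 <- array(stats::rnorm(length(x), 0, sigma), dim(x))
  sqrt((x + n1)^2 + n2^2)
}

#' Generate a synthetic acquisition bundle from a phantom spec
#'
#' Forward-simulates, for every region of the phantom: monoexponential
#' multi-echo GRE and SE decays (`S(TE) = S0 exp(-R TE)`), the DWI pair
#' (`S_b = S0 exp(-b ADC)`), and the paired GE/SE DSC series via
#' [forwardDsc()]. Arterial voxels carry the pure AIF. Rician (or
#' Gaussian) noise with SD `s0 / snr` is applied to signal magnitudes —
#' not to derived quantities — honoring the seed.
#'
#' @param spec a [phantomSpec()].
#' @return list with `bundle` (named rawdata: `gre`, `mese` [EchoSeries],
#'   `dsc_ge`, `dsc_se` [DynamicSeries], `dwi_b0`, `dwi_b` [VolumeImage],
#'   `roi`, `brain` masks) and `truth` (ground-truth [VolumeImage] per
#'   parameter, integer `labels`, the AIF curve, and the per-region
#'   parameter table).
#' @export
generatePhantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  d <- spec$dim
  affine <- diag(c(spec$voxel_mm, 1))
  reg <- .phantom_geometry(spec)
  pre <- spec$presets
  times <- (seq_len(spec$n_time) - 1) * spec$tr_s
  classes <- c("glycolysis", "oxphos", "necrosis", "hypoxia_nv",
               "hypoxia_nonv")

  param_of <- function(id, what) {
    # id: -1 artery, 0 wm, 1..5 tumor classes
    key <- if (id == 0) "wm" else classes[id]
    pre[key, what]
  }

  nvox <- prod(d)
  gre <- array(0, c(d, length(spec$te_gre_s)))
  mese <- array(0, c(d, length(spec$te_mese_s)))
  dsc_ge <- array(0, c(d, spec$n_time))
  dsc_se <- array(0, c(d, spec$n_time))
  b0 <- array(0, d); bb <- array(0, d)
  truth_names <- c("cbv", "cbf", "adc", "r2", "r2star", "oef")
  truth <- lapply(truth_names, function(x) array(NA_real_, d))
  names(truth) <- truth_names
  region_tab <- list()

  aif_curve <- gammaVariate(times, spec$aif$k, spec$aif$t0, spec$aif$alpha,
                            spec$aif$beta)

  for (id in sort(unique(as.vector(reg)))) {
    vox <- which(reg == id)
    if (id == -1) {                       # arterial voxels: pure AIF
      ge <- aif_curve; se <- 0.6 * aif_curve
      s0r <- spec$s0_artery
      r2 <- 10; r2s <- 30; adc <- 3.0e-3
    } else {
      fw <- forwardDsc(param_of(id, "cbv"), param_of(id, "cbf"), spec$aif,
                       times, param_of(id, "loop_direction"),
                       param_of(id, "lag_s"), param_of(id, "qmax_target"),
                       spec$te_ge_s, spec$te_se_s, spec$s0)
      ge <- fw$ge_dr2; se <- fw$se_dr2
      s0r <- spec$s0
      r2 <- param_of(id, "r2"); r2s <- param_of(id, "r2star")
      adc <- param_of(id, "adc")
      for (nm in truth_names)
        truth[[nm]][vox] <- param_of(id, switch(nm, r2star = "r2star", nm))
      region_tab[[length(region_tab) + 1]] <- data.frame(
        region = if (id == 0) "wm" else classes[id], n_voxels = length(vox))
    }
    for (j in seq_along(spec$te_gre_s))
      gre[vox + (j - 1) * nvox] <- s0r * exp(-r2s * spec$te_gre_s[j])
    for (j in seq_along(spec$te_mese_s))
      mese[vox + (j - 1) * nvox] <- s0r * exp(-r2 * spec$te_mese_s[j])
    for (j in seq_len(spec$n_time)) {
      dsc_ge[vox + (j - 1) * nvox] <- s0r * exp(-ge[j] * spec$te_ge_s)
      dsc_se[vox + (j - 1) * nvox] <- s0r * exp(-se[j] * spec$te_se_s)
    }
    b0[vox] <- s0r
    bb[vox] <- s0r * exp(-spec$b_value * adc)
  }

  sigma <- if (is.finite(spec$snr)) spec$s0 / spec$snr else 0
  gre <- .add_noise(gre, sigma, spec$noise_model)
  mese <- .add_noise(mese, sigma, spec$noise_model)
  dsc_ge <- .add_noise(dsc_ge, sigma, spec$noise_model)
  dsc_se <- .add_noise(dsc_se, sigma, spec$noise_model)
  b0 <- .add_noise(b0, sigma, spec$noise_model)
  bb <- .add_noise(bb, sigma, spec$noise_model)

  labels <- array(0L, d)
  labels[reg > 0] <- reg[reg > 0]
  roi <- array(as.numeric(reg > 0), d)
  brain <- array(1, d)

  truth_vols <- lapply(names(truth), function(nm)
    volumeImage(truth[[nm]], affine = affine, name = paste0("truth_", nm),
                units = switch(nm, cbv = "fraction", cbf = "mL/100g/min",
                               adc = "mm^2/s", "1/s")))
  names(truth_vols) <- names(truth)

  list(
    bundle = list(
      gre = echoSeries(gre, spec$te_gre_s, affine),
      mese = echoSeries(mese, spec$te_mese_s, affine),
      dsc_ge = dynamicSeries(dsc_ge, spec$tr_s, spec$te_ge_s,
                             spec$n_baseline, affine),
      dsc_se = dynamicSeries(dsc_se, spec$tr_s, spec$te_se_s,
                             spec$n_baseline, affine),
      dwi_b0 = volumeImage(b0, affine = affine, units = "a.u.",
                           name = "dwi_b0"),
      dwi_b = volumeImage(bb, affine = affine, units = "a.u.",
                          name = "dwi_b1000"),
      roi = volumeImage(roi, affine = affine, units = "mask", name = "roi"),
      brain = volumeImage(brain, affine = affine, units = "mask",
                          name = "brain")),
    truth = list(
      maps = truth_vols,
      labels = volumeImage(labels + 0, affine = affine, units = "label",
                           name = "truth_labels"),
      aif = data.frame(time_s = times, dr2 = aif_curve),
      regions = do.call(rbind, region_tab),
      spec = spec))
}

#' Write a phantom bundle to a directory as NIfTI + JSON
#'
#' @param phantom result of [generatePhantom()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writePhantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  b <- phantom$bundle
  for (nm in names(b))
    writeVolume(b[[nm]], file.path(dir, paste0(nm, ".nii.gz")))
  for (nm in names(phantom$truth$maps))
    writeVolume(phantom$truth$maps[[nm]],
                file.path(dir, paste0("truth_", nm, ".nii.gz")))
  writeVolume(phantom$truth$labels, file.path(dir, "truth_labels.nii.gz"))
  utils::write.csv(phantom$truth$aif, file.path(dir, "truth_aif.csv"),
                   row.names = FALSE)
  spec <- phantom$truth$spec
  meta <- spec[setdiff(names(spec), c("presets", "aif"))]
  meta$aif <- spec$aif
  jsonlite::write_json(meta, file.path(dir, "phantom_spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
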