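# End-to-end pipeline: raw series bundle -> biomarker maps -> TME map ->
# compartment summary, with optional NIfTI/CSV/JSON output.

# fit gamma-variates for every masked voxel; returns parameter matrix and
# fitted curves on the acquisition grid
.fit_gamma_all <- function(times, dr2, n_baseline, cfg_dsc) {
  nvox <- ncol(dr2)
  par <- matrix(NA_real_, nvox, 7,
                dimnames = list(NULL, c("k", "t0", "alpha", "beta",
                                        "fit_error", "peak", "integral")))
  fitted <- matrix(0, nrow(dr2), nvox)
  valid <- logical(nvox)
  winsum <- rep(NA_real_, nvox)   # raw-curve sum over the first-pass window
  # common first-pass window and arrival prior from the global mean curve:
  # bolus timing is global up to small arrival shifts, and a fixed window
  # stabilizes the per-voxel fits against noise
  finite_vox <- colSums(!is.finite(dr2)) == 0
  gstart <- NULL; arrival <- NULL
  nt <- nrow(dr2)
  if (any(finite_vox)) {
    gm <- rowMeans(dr2[, finite_vox, drop = FALSE])
    gw <- firstPassWindow(gm, n_baseline, cfg_dsc$detection_smooth)
    gstart <- max(1, gw[1] - 2)
    arrival <- times[gw[1]]
  }
  sm <- .movavg_mat(dr2, cfg_dsc$detection_smooth)
  for (v in seq_len(nvox)) {
    y <- dr2[, v]
    if (any(!is.finite(y))) next
    win <- NULL
    if (!is.null(gstart)) {
      # global start (bolus timing is shared), per-voxel tail end so that
      # long-MTT voxels are not truncated: stop at the first sample below
      # 5% of the voxel peak, or at a local minimum that dips below half
      # peak (a recirculation valley)
      ysv <- sm[, v]
      rng <- gstart:nt
      pkv <- rng[which.max(ysv[rng])]
      e <- pkv
      thr <- 0.05 * ysv[pkv]
      while (e < nt) {
        # stop at the tail only on two consecutive sub-threshold samples
        # (a single noise dip must not truncate a slow washout), or at a
        # recirculation valley below half peak
        if (ysv[e + 1] < thr && (e + 2 > nt || ysv[e + 2] < thr)) break
        if (e + 2 <= nt && ysv[e + 1] > ysv[e] && ysv[e + 2] > ysv[e + 1] &&
            ysv[e] < 0.5 * ysv[pkv]) break
        e <- e + 1
      }
      win <- gstart:e
    }
    f <- fitGammaVariate(y, times_s = times, n_baseline = n_baseline,
                         detection_k = cfg_dsc$detection_k,
                         smooth = cfg_dsc$detection_smooth,
                         refine = isTRUE(cfg_dsc$refine_fits),
                         window = win, arrival_s = arrival)
    if (!f$valid) next
    valid[v] <- TRUE
    par[v, ] <- c(f$k, f$t0, f$alpha, f$beta, f$fit_error, f$peak,
                  f$integral)
    fitted[, v] <- gammaVariate(times, f$k, f$t0, f$alpha, f$beta)
    # first-pass area: raw samples over the window (unbiased, low
    # variance) plus the fitted tail beyond it (long-MTT voxels whose
    # curve has not returned to baseline by the window end)
    wv <- if (is.null(win)) f$window else win
    tail_int <- f$integral / (times[2] - times[1]) -
      sum(gammaVariate(times[wv], f$k, f$t0, f$alpha, f$beta))
    winsum[v] <- sum(y[wv]) + max(0, tail_int)
  }
  fitted[, !valid] <- NA
  list(par = par, fitted = fitted, valid = valid, winsum = winsum)
}

# per-voxel MTI from paired gamma fits, evaluated on a fine common grid
.mti_from_fits <- function(ge_par, se_par, valid, n_fine = 128) {
  nvox <- nrow(ge_par)
  mti <- rep(NA_real_, nvox)
  for (v in which(valid)) {
    g <- ge_par[v, ]; s <- se_par[v, ]
    t_start <- min(g["t0"], s["t0"])
    t_end <- max(
      g["t0"] + stats::qgamma(0.995, g["alpha"] + 1, scale = g["beta"]),
      s["t0"] + stats::qgamma(0.995, s["alpha"] + 1, scale = s["beta"]))
    tf <- seq(t_start, t_end, length.out = n_fine)
    ge <- gammaVariate(tf, g["k"], g["t0"], g["alpha"], g["beta"])
    se <- gammaVariate(tf, s["k"], s["t0"], s["alpha"], s["beta"])
    mti[v] <- computeMti(buildVhl(ge, se))
  }
  mti
}

#' Compute all biomarker maps from a raw acquisition bundle
#'
#' Runs relaxometry (R2*, R2), diffusion (ADC), dual-echo DSC perfusion
#' (gamma-variate fitting, AIF selection, CBV/CBF), vascular architecture
#' (MTI, Q_max, MVD, VSI) and oxygen metabolism (OEF, CMRO2, PO2) on a
#' bundle of co-registered series, as produced by [generatePhantom()] or
#' assembled from [readVolume()] calls.
#'
#' @param bundle named list: `gre`, `mese` ([EchoSeries]), `dsc_ge`,
#'   `dsc_se` ([DynamicSeries]), `dwi_b0`, `dwi_b` ([VolumeImage]),
#'   optional `brain` and `roi` masks.
#' @param config pipeline configuration ([defaultConfig()]).
#' @return named list of [VolumeImage] maps (`r2star`, `r2`, `adc`, `cbv`,
#'   `cbf`, `oef`, `cmro2`, `po2`, `mti`, `qmax`, `mvd`, `vsi`), plus
#'   `aif` (curve + fit + source voxels) and `gamma_par` (per-voxel fit
#'   parameter matrices).
#' @export
fitBiomarkers <- function(bundle, config = defaultConfig()) {
  need <- c("gre", "mese", "dsc_ge", "dsc_se", "dwi_b0", "dwi_b")
  if (!all(need %in% names(bundle)))
    stop("bundle must contain: ", paste(need, collapse = ", "))
  dims <- dim(bundle$gre@data)[1:3]
  for (nm in need)
    if (!identical(dim(imgData(bundle[[nm]]))[1:3], dims))
      stop("series '", nm, "' is not on the common acquisition grid")
  cns <- config$constants
  affine <- bundle$gre@affine
  brain <- if (!is.null(bundle$brain)) bundle$brain else NULL

  if (isTRUE(config$preprocess$spatial_smooth)) {
    sz <- config$preprocess$smooth_size
    roi <- bundle$roi
    sm4 <- function(x) smoothSeriesRoi(x, roi, sz)
    bundle$gre <- echoSeries(sm4(bundle$gre@data), bundle$gre@echoTimes,
                             affine)
    bundle$mese <- echoSeries(sm4(bundle$mese@data), bundle$mese@echoTimes,
                              affine)
    for (nm in c("dsc_ge", "dsc_se")) {
      s <- bundle[[nm]]
      bundle[[nm]] <- dynamicSeries(sm4(s@data), s@trS, s@teS, s@nBaseline,
                                    affine)
    }
    for (nm in c("dwi_b0", "dwi_b")) {
      v <- bundle[[nm]]
      arr <- smoothSeriesRoi(array(v@data, c(dim(v@data), 1)), roi, sz)
      bundle[[nm]] <- volumeImage(array(arr, dim(v@data)), affine = affine,
                                  units = v@units, name = v@name)
    }
  }

  r2star <- mapRelaxation(bundle$gre, brain,
                          weighted = config$relaxometry$weighted,
                          name = "r2star")
  r2 <- mapRelaxation(bundle$mese, brain,
                      drop_first_echo = config$relaxometry$drop_first_se_echo,
                      weighted = config$relaxometry$weighted, name = "r2")
  adc <- mapAdc(bundle$dwi_b0, bundle$dwi_b, config$adc$b_value, brain)

  ge <- signalToDeltaR2(bundle$dsc_ge, brain)
  se <- signalToDeltaR2(bundle$dsc_se, brain)
  cfg <- config$dsc

  if (identical(cfg$aif_mode, "supplied")) {
    if (is.null(cfg$aif_curve))
      stop("aif_mode = 'supplied' but config$dsc$aif_curve is missing")
    aif_raw <- cfg$aif_curve
    aif_vox <- integer()
  } else {
    sel <- selectAif(ge$dr2, ge$times, ge$n_baseline,
                     mask = if (!is.null(brain)) brain@data else NULL,
                     top_n = cfg$aif_top_n)
    aif_raw <- sel$curve$delta_r2
    aif_vox <- sel$voxels
  }
  aif_fit <- fitGammaVariate(aif_raw, times_s = ge$times,
                             n_baseline = ge$n_baseline,
                             detection_k = cfg$detection_k,
                             smooth = cfg$detection_smooth, refine = TRUE)
  if (!aif_fit$valid) stop("AIF gamma-variate fit failed")
  aif_fitted <- gammaVariate(ge$times, aif_fit$k, aif_fit$t0,
                             aif_fit$alpha, aif_fit$beta)

  if (isTRUE(cfg$leakage_correction)) {
    roi_vec <- if (!is.null(bundle$roi)) as.vector(bundle$roi@data > 0)
               else rep(FALSE, prod(dims))
    ref_ok <- !roi_vec & colSums(!is.finite(ge$dr2)) == 0
    if (any(ref_ok)) {
      ref <- rowMeans(ge$dr2[, ref_ok, drop = FALSE])
      for (v in which(roi_vec)) {
        lc <- correctLeakage(ge$dr2[, v], ref, ge$times)
        ge$dr2[, v] <- lc$dr2
      }
    }
  }

  gf <- .fit_gamma_all(ge$times, ge$dr2, ge$n_baseline, cfg)
  sf <- .fit_gamma_all(se$times, se$dr2, se$n_baseline, cfg)

  perf <- computeCbvCbf(gf$fitted, aif_fitted, bundle$dsc_ge@trS, cns,
                        svd_threshold = cfg$svd_threshold)
  # CBV from the raw-curve integral over the first-pass window: under
  # noise the direct integral is an unbiased, lower-variance estimator
  # than the fitted-curve integral (the fit is kept for deconvolution,
  # Q_max and the VHL, where smoothness matters)
  aif_int <- aif_fit$integral
  perf$cbv <- dscScaling(cns)$k_h * gf$winsum * bundle$dsc_ge@trS / aif_int
  perf$cbv[!gf$valid] <- NA

  both <- gf$valid & sf$valid
  qmax <- rep(NA_real_, prod(dims))
  den_pk <- if (isTRUE(cfg$qmax_literal)) gf$par[, "peak"] else sf$par[, "peak"]
  ok <- both & is.finite(den_pk) & den_pk > 0
  qmax[ok] <- gf$par[ok, "peak"] / den_pk[ok]^1.5
  mti <- .mti_from_fits(gf$par, sf$par, both)

  mvd <- computeMvd(qmax, perf$cbv, as.vector(adc@data), cns)
  vsi <- computeVsi(qmax, perf$cbv, as.vector(adc@data), cns)

  oef <- computeOef(as.vector(r2star@data), as.vector(r2@data), perf$cbv, cns)
  cmro2 <- computeCmro2(oef, perf$cbf, cns)
  po2 <- computePo2(oef, cmro2, cns,
                    clamp_zero = isTRUE(config$po2_clamp_zero))

  vol <- function(x, name, units)
    volumeImage(array(x, dims), affine = affine, units = units, name = name)
  list(
    r2star = r2star, r2 = r2, adc = adc,
    cbv = vol(perf$cbv, "cbv", "fraction"),
    cbf = vol(perf$cbf, "cbf", "mL/100g/min"),
    oef = vol(oef, "oef", "fraction"),
    cmro2 = vol(cmro2, "cmro2", "umol/100g/min"),
    po2 = vol(po2, "po2", "mmHg"),
    mti = vol(mti, "mti", "s^-5/2"),
    qmax = vol(qmax, "qmax", "s^1/2"),
    mvd = vol(mvd, "mvd", "mm^-2"),
    vsi = vol(vsi, "vsi", "um"),
    aif = list(times = ge$times, raw = aif_raw, fitted = aif_fitted,
               fit = aif_fit, voxels = aif_vox),
    gamma_par = list(ge = gf$par, se = sf$par))
}

#' Summarize TME compartments over an ROI
#'
#' Percentages are voxel counts over the whole ROI (voxel size is constant
#' within an acquisition, so counts and volumes are proportional);
#' unclassified voxels stay in the denominator unless
#' `classified_only = TRUE`. Derived aggregates: vital tumor (= active
#' tumor) = glycolysis + OxPhos; total hypoxia = hypoxia with NV +
#' hypoxia without NV.
#'
#' @param tme_map a [TMEMap].
#' @param roi_mask ROI ([VolumeImage] or logical array); defaults to all
#'   nonzero labels' support being impossible, so pass the mask used for
#'   classification.
#' @param classified_only exclude unclassified voxels from the denominator.
#' @return a [CompartmentSummary].
#' @export
summarizeRoi <- function(tme_map, roi_mask, classified_only = FALSE) {
  lab <- tme_map@labels@data
  roi <- .mask_array(roi_mask, dim(lab), tme_map@labels)
  labs <- lab[roi]
  if (!length(labs)) stop("empty ROI")
  counts <- as.integer(table(factor(labs, levels = 0:5)))
  names(counts) <- c("unclassified", "glycolysis", "oxphos", "necrosis",
                     "hypoxia_nv", "hypoxia_nonv")
  denom <- if (classified_only) sum(counts[-1]) else sum(counts)
  if (denom == 0) denom <- 1L
  pct <- 100 * counts / denom
  pct <- pct[c("glycolysis", "oxphos", "necrosis", "hypoxia_nv",
               "hypoxia_nonv", "unclassified")]
  if (classified_only) pct["unclassified"] <- 0
  derived <- c(vital_tumor = unname(pct["glycolysis"] + pct["oxphos"]),
               active_tumor = unname(pct["glycolysis"] + pct["oxphos"]),
               total_hypoxia = unname(pct["hypoxia_nv"] + pct["hypoxia_nonv"]))
  new("CompartmentSummary", percent = pct, derived = derived,
      counts = counts[names(pct)], nVoxels = length(labs))
}

.load_bundle <- function(inputs) {
  if (!is.null(inputs$gre) && is(inputs$gre, "EchoSeries")) return(inputs)
  rd4 <- function(p) readVolume(p, expect_dims = 4L)
  b <- list()
  g <- rd4(inputs$gre)
  b$gre <- echoSeries(unclass(g), inputs$te_gre_s, attr(g, "affine"))
  m <- rd4(inputs$mese)
  b$mese <- echoSeries(unclass(m), inputs$te_mese_s, attr(m, "affine"))
  dg <- rd4(inputs$dsc_ge)
  b$dsc_ge <- dynamicSeries(unclass(dg), inputs$tr_s, inputs$te_ge_s,
                            inputs$n_baseline, attr(dg, "affine"))
  ds <- rd4(inputs$dsc_se)
  b$dsc_se <- dynamicSeries(unclass(ds), inputs$tr_s, inputs$te_se_s,
                            inputs$n_baseline, attr(ds, "affine"))
  b$dwi_b0 <- readVolume(inputs$dwi_b0)
  b$dwi_b <- readVolume(inputs$dwi_b)
  b$roi <- readVolume(inputs$roi, units = "mask")
  if (!is.null(inputs$brain)) b$brain <- readVolume(inputs$brain,
                                                    units = "mask")
  b
}

#' Run the full TME-mapping pipeline
#'
#' Chains [fitBiomarkers()], [buildTmeMap()] and [summarizeRoi()] and,
#' when `out_dir` is set, writes every biomarker map, the TME map with its
#' JSON legend, the OEF-CMRO2 scatter table, the AIF, the compartment
#' summary CSV and a JSON provenance record of the constants and options
#' actually used. Deterministic given the config (the seed is set at
#' entry and recorded).
#'
#' @param inputs a bundle (in-memory, see [fitBiomarkers()]) or a named
#'   list of file paths plus acquisition parameters (`te_gre_s`,
#'   `te_mese_s`, `tr_s`, `te_ge_s`, `te_se_s`, `n_baseline`).
#' @param config pipeline configuration.
#' @param out_dir output directory, or NULL to skip writing.
#' @return list with `maps`, `tme` ([TMEMap]), `summary`
#'   ([CompartmentSummary]), and `out_dir`.
#' @export
runPipeline <- function(inputs, config = defaultConfig(), out_dir = NULL) {
  set.seed(config$seed)
  bundle <- .load_bundle(inputs)
  if (is.null(bundle$roi)) stop("inputs must include an ROI mask")
  maps <- fitBiomarkers(bundle, config)
  rules <- classificationRules()
  cls_maps <- maps[c("oef", "cmro2", "mti", "mvd", "po2")]
  if (isTRUE(config$classification$median_filter)) {
    cls_maps <- lapply(cls_maps, medianFilterRoi, roi = bundle$roi,
                       size = config$classification$median_filter_size)
    # PO2 is a deterministic function of OEF and CMRO2; recompute it from
    # the filtered inputs so the maps stay mutually consistent
    cls_maps$po2 <- volumeImage(
      array(computePo2(as.vector(cls_maps$oef@data),
                       as.vector(cls_maps$cmro2@data), config$constants,
                       clamp_zero = isTRUE(config$po2_clamp_zero)),
            dim(cls_maps$oef@data)),
      affine = cls_maps$oef@affine, units = "mmHg", name = "po2")
  }
  tme <- buildTmeMap(cls_maps, bundle$roi, rules)
  summ <- summarizeRoi(tme, bundle$roi)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in c("r2star", "r2", "adc", "cbv", "cbf", "oef", "cmro2",
                 "po2", "mti", "qmax", "mvd", "vsi"))
      writeVolume(maps[[nm]], file.path(out_dir, paste0(nm, ".nii.gz")))
    writeVolume(tme@labels, file.path(out_dir, "tme_map.nii.gz"))
    jsonlite::write_json(tme@legend, file.path(out_dir, "tme_legend.json"))
    utils::write.csv(oefCmro2Scatter(tme),
                     file.path(out_dir, "oef_cmro2_scatter.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(time_s = maps$aif$times,
                                dr2_raw = maps$aif$raw,
                                dr2_fitted = maps$aif$fitted),
                     file.path(out_dir, "aif.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(summ),
                     file.path(out_dir, "compartment_summary.csv"),
                     row.names = FALSE)
    prov <- list(package_version = as.character(utils::packageVersion("tmemap")),
                 seed = config$seed,
                 constants = config$constants,
                 thresholds = config$thresholds,
                 dsc = config$dsc[setdiff(names(config$dsc), "aif_curve")],
                 mti_sign_convention =
                   "clockwise VHL (x right, y up) = positive MTI")
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(maps = maps, tme = tme, summary = summ, out_dir = out_dir)
}
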