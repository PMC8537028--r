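# Voxelwise five-class TME classification from OEF, CMRO2, PO2, MTI, MVD.

#' Classify tissue oxygen tension into bands
#'
#' Hypoxia below 10 mmHg, normoxia for the closed band 10-60 mmHg, high
#' oxygen tension above 60 mmHg. Both band endpoints belong to normoxia.
#'
#' @param po2 tissue oxygen tension (mmHg), vectorized.
#' @param hypoxia,hyperoxia band limits (mmHg).
#' @return character vector in `{"hypoxic","normoxic","hyperoxic"}` (`NA`
#'   for non-finite input).
#' @export
classifyPo2Band <- function(po2, hypoxia = 10, hyperoxia = 60) {
  out <- ifelse(po2 < hypoxia, "hypoxic",
                ifelse(po2 <= hyperoxia, "normoxic", "hyperoxic"))
  out[!is.finite(po2)] <- NA_character_
  out
}

#' Classify neovascularization status from MTI and MVD
#'
#' No (functional) neovascularization if `|MTI| <= mti_limit` or
#' `MVD < mvd_limit`; functional neovascularization otherwise. The "or"
#' follows the rule that either a near-zero hysteresis-loop area or a low
#' microvessel density marks absent/dysfunctional tumor vasculature.
#'
#' @param mti microvessel type indicator (s^-5/2), vectorized.
#' @param mvd microvessel density (mm^-2).
#' @param mti_limit,mvd_limit thresholds (5.0 s^-5/2, 250 mm^-2).
#' @return character vector in `{"functional_NV","no_NV"}`.
#' @export
classifyNeovascularization <- function(mti, mvd, mti_limit = 5.0,
                                       mvd_limit = 250) {
  out <- ifelse(abs(mti) <= mti_limit | mvd < mvd_limit,
                "no_NV", "functional_NV")
  out[!is.finite(mti) | !is.finite(mvd)] <- NA_character_
  out
}

# logical matrix (voxels x classes) of rule matches; strict bounds
.match_rules <- function(cmro2, oef_percent, mti, mvd, po2, rules) {
  mti_lim <- attr(rules, "mti_limit")
  mvd_lim <- attr(rules, "mvd_limit")
  band <- classifyPo2Band(po2)
  n <- length(cmro2)
  hit <- matrix(FALSE, n, nrow(rules))
  colnames(hit) <- rules$class
  finite <- is.finite(cmro2) & is.finite(oef_percent) & is.finite(mti) &
    is.finite(mvd)
  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    ok <- finite &
      cmro2 > r$cmro2_lo & cmro2 < r$cmro2_hi &
      oef_percent > r$oef_lo & oef_percent < r$oef_hi
    ok <- ok & if (r$nv) (abs(mti) > mti_lim & mvd > mvd_lim)
               else      (abs(mti) < mti_lim & mvd < mvd_lim)
    if (!is.na(r$po2_band)) ok <- ok & !is.na(band) & band == r$po2_band
    hit[, i] <- ok
  }
  hit
}

#' Classify a voxel (or vector of voxels) into a TME compartment
#'
#' Applies the five per-class predicates in precedence order
#' necrosis -> hypoxia without NV -> hypoxia with NV -> glycolysis ->
#' OxPhos; the first matching class wins (necrosis first resolves its
#' genuine overlap with hypoxia-without-NV, since its OEF criterion is the
#' stricter one). Voxels matching no rule, or with any invalid biomarker,
#' get label 0 (unclassified).
#'
#' @param cmro2 umol/100g/min.
#' @param oef_percent OEF in percent (100 x fraction).
#' @param mti s^-5/2.
#' @param mvd mm^-2.
#' @param po2 mmHg.
#' @param rules from [classificationRules()] (rows in precedence order).
#' @return integer labels: 0 unclassified, 1 glycolysis, 2 OxPhos,
#'   3 necrosis, 4 hypoxia with NV, 5 hypoxia without NV.
#' @export
classifyVoxel <- function(cmro2, oef_percent, mti, mvd, po2,
                          rules = classificationRules()) {
  hit <- .match_rules(cmro2, oef_percent, mti, mvd, po2, rules)
  first <- apply(hit, 1, function(h) {
    w <- which(h)
    if (length(w)) w[1] else 0L
  })
  ifelse(first > 0, rules$label[pmax(first, 1)], 0L)
}

#' Audit the classification rule system over a dense biomarker grid
#'
#' Sweeps CMRO2, OEF, MTI and MVD over dense grids, derives PO2 from the
#' Hill model, applies all five predicates and reports which fraction of
#' combinations matches zero or multiple classes. Overlaps exist by
#' construction (necrosis vs hypoxia-without-NV) and are resolved by the
#' precedence order; gaps (e.g. CMRO2 < 80 with OEF 50-75) remain
#' unclassified.
#'
#' @param cmro2_grid,oef_grid,mti_grid,mvd_grid sweep values.
#' @param rules classification rules.
#' @return list with `frac_none`, `frac_multi`, `n`.
#' @export
auditRules <- function(cmro2_grid = seq(0, 400, by = 10),
                       oef_grid = seq(0, 100, by = 2.5),
                       mti_grid = seq(-30, 30, by = 5),
                       mvd_grid = seq(0, 600, by = 50),
                       rules = classificationRules()) {
  g <- expand.grid(cmro2 = cmro2_grid, oef = oef_grid, mti = mti_grid,
                   mvd = mvd_grid)
  po2 <- computePo2(g$oef / 100, g$cmro2)
  hit <- .match_rules(g$cmro2, g$oef, g$mti, g$mvd, po2, rules)
  nmatch <- rowSums(hit)
  list(frac_none = mean(nmatch == 0), frac_multi = mean(nmatch > 1),
       n = nrow(g))
}

#' Mask-aware in-plane spatial smoothing of a 4D series
#'
#' Normalized in-plane box smoothing of every volume of a 4D acquisition,
#' restricted so that averaging never crosses the ROI boundary (each voxel
#' averages only neighbors on its own side of the mask). Standard
#' preprocessing for voxelwise DSC/qBOLD fitting: it trades in-plane
#' resolution for per-curve noise, and the mask restriction keeps tumor
#' and brain signal pools separate, so uniform regions are reproduced
#' exactly.
#'
#' @param data4d 4D array (x, y, z, t/echo).
#' @param roi ROI mask (array or [VolumeImage]); NULL smooths everything
#'   as one pool.
#' @param size odd in-plane window edge length (default 3).
#' @return smoothed 4D array.
#' @export
smoothSeriesRoi <- function(data4d, roi = NULL, size = 3) {
  stopifnot(size %% 2 == 1, length(dim(data4d)) == 4)
  d <- dim(data4d)
  g <- if (is.null(roi)) array(TRUE, d[1:3]) else .mask_array(roi, d[1:3],
                                                              NULL)
  half <- (size - 1) / 2
  out <- array(0, d)
  for (grp in unique(as.vector(g))) {
    ind <- array(as.numeric(g == grp), d[1:3])
    num <- array(0, d); den <- array(0, d[1:3])
    for (dx in -half:half) for (dy in -half:half) {
      sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
      tx <- max(1, 1 - dx):min(d[1], d[1] - dx)
      sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
      ty <- max(1, 1 - dy):min(d[2], d[2] - dy)
      den[tx, ty, ] <- den[tx, ty, ] + ind[sx, sy, , drop = FALSE]
      num[tx, ty, , ] <- num[tx, ty, , , drop = FALSE] +
        data4d[sx, sy, , , drop = FALSE] *
        as.vector(ind[sx, sy, , drop = FALSE])
    }
    sel <- as.vector(ind) > 0
    for (j in seq_len(d[4])) {
      slab <- num[, , , j]
      out[, , , j][sel] <- slab[sel] / den[sel]
    }
  }
  out
}

#' ROI-restricted in-plane median filtering of a biomarker map
#'
#' Replaces each ROI voxel by the median of the finite values in its
#' in-plane `size x size` neighborhood intersected with the ROI. Standard
#' edge-preserving noise reduction for voxelwise parameter maps: on a
#' region of constant value the filter is exact (the median of identical
#' values), so it does not blur compartments into each other across the
#' ROI boundary, and isolated failed-fit voxels are filled from their
#' neighborhood. Voxels outside the ROI are untouched.
#'
#' @param vol a [VolumeImage].
#' @param roi ROI mask ([VolumeImage] or logical array).
#' @param size odd window edge length (default 3).
#' @return filtered [VolumeImage].
#' @export
medianFilterRoi <- function(vol, roi, size = 3) {
  stopifnot(size %% 2 == 1)
  d <- dim(vol@data)
  m <- .mask_array(roi, d, vol)
  x <- vol@data
  x[!m] <- NA
  half <- (size - 1) / 2
  # stack shifted copies in-plane and take the voxelwise median
  stack <- array(NA_real_, c(d, size * size))
  s <- 0
  for (dx in -half:half) for (dy in -half:half) {
    s <- s + 1
    sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
    tx <- max(1, 1 - dx):min(d[1], d[1] - dx)
    sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
    ty <- max(1, 1 - dy):min(d[2], d[2] - dy)
    stack[tx, ty, , s] <- x[sx, sy, , drop = FALSE]
  }
  med <- apply(stack, 1:3, stats::median, na.rm = TRUE)
  med[is.nan(med)] <- NA
  out <- vol@data
  out[m] <- med[m]
  volumeImage(out, affine = vol@affine, units = vol@units, name = vol@name)
}

#' Build a TME map from biomarker maps
#'
#' Voxelwise classification inside the ROI; voxels outside the ROI or with
#' any invalid biomarker get label 0. Also attaches the per-voxel
#' OEF-CMRO2 scatter table (with labels) that backs the standard
#' OEF-CMRO2 scatter plot.
#'
#' @param biomarkers named list of [VolumeImage]s: `oef` (fraction),
#'   `cmro2`, `mti`, `mvd`, `po2`, all on one grid.
#' @param roi_mask [VolumeImage] or logical array.
#' @param rules classification rules.
#' @return a [TMEMap]; the scatter table is in `attr(, "scatter")` of the
#'   legend-carrying object, accessible via [oefCmro2Scatter()].
#' @export
buildTmeMap <- function(biomarkers, roi_mask, rules = classificationRules()) {
  need <- c("oef", "cmro2", "mti", "mvd", "po2")
  stopifnot(all(need %in% names(biomarkers)))
  dims <- dim(biomarkers$oef@data)
  for (nm in need)
    if (!identical(dim(biomarkers[[nm]]@data), dims))
      stop("biomarker map '", nm, "' is not on the common grid")
  roi <- .mask_array(roi_mask, dims, biomarkers$oef)
  idx <- which(roi)
  lab <- array(0L, dims)
  oefp <- 100 * biomarkers$oef@data[idx]
  if (length(idx)) {
    lab[idx] <- classifyVoxel(biomarkers$cmro2@data[idx], oefp,
                              biomarkers$mti@data[idx],
                              biomarkers$mvd@data[idx],
                              biomarkers$po2@data[idx], rules)
  }
  legend <- data.frame(
    label = 0:5,
    class = c("unclassified", "glycolysis", "oxphos", "necrosis",
              "hypoxia_nv", "hypoxia_nonv"),
    color = c("gray", "blue", "green", "black", "yellow", "red"),
    stringsAsFactors = FALSE)
  scatter <- data.frame(voxel = idx, oef_percent = oefp,
                        cmro2 = biomarkers$cmro2@data[idx],
                        label = lab[idx])
  map <- new("TMEMap",
             labels = volumeImage(lab, affine = biomarkers$oef@affine,
                                  units = "label", name = "tme_map"),
             legend = legend)
  attr(map, "scatter") <- scatter
  map
}

#' Per-voxel OEF-CMRO2 scatter table of a TME map
#'
#' @param map a [TMEMap] produced by [buildTmeMap()].
#' @return data.frame with voxel index, OEF (%), CMRO2 and label.
#' @export
oefCmro2Scatter <- function(map) {
  s <- attr(map, "scatter")
  if (is.null(s)) stop("map carries no scatter table")
  s
}
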