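# qBOLD oxygen metabolism: OEF, CMRO2 and tissue oxygen tension PO2.

#' Oxygen extraction fraction (qBOLD)
#'
#' `OEF = (R2* - R2) / (k CBV)` with
#' `k = (4/3) pi gamma delta_chi Hct B0` (see [qboldK()]). The reversible
#' dephasing rate R2' = R2* - R2 is attributed to deoxygenated blood
#' occupying the fraction CBV of the voxel. Voxels with non-positive CBV,
#' or with R2* < R2 (noise), are flagged invalid (`NA`).
#'
#' @param r2star,r2 transverse relaxation rates (1/s).
#' @param cbv blood-volume fraction.
#' @param c constants from [physioConstants()].
#' @return OEF as a fraction (vectorized).
#' @export
computeOef <- function(r2star, r2, cbv, c = physioConstants()) {
  oef <- (r2star - r2) / (qboldK(c) * cbv)
  oef[!is.finite(oef) | cbv <= 0 | (r2star - r2) < 0] <- NA
  oef
}

#' Cerebral metabolic rate of oxygen
#'
#' Fick's principle: `CMRO2 = C_a CBF OEF`, with the arterial oxygen
#' content C_a in umol O2 per mL blood and CBF in mL/100g/min, so CMRO2
#' lands in umol/100g/min.
#'
#' @param oef oxygen extraction fraction.
#' @param cbf cerebral blood flow (mL/100g/min).
#' @param c constants from [physioConstants()].
#' @return CMRO2 in umol/100g/min (vectorized).
#' @export
computeCmro2 <- function(oef, cbf, c = physioConstants()) {
  out <- c$ca * cbf * oef
  out[!is.finite(out) | oef < 0 | cbf < 0] <- NA
  out
}

#' Tissue oxygen tension from OEF and CMRO2
#'
#' Inverts the Hill model of hemoglobin-O2 dissociation and subtracts the
#' diffusion-limited drop:
#' `PO2 = p50 (2/OEF - 1)^(1/h) - CMRO2 / L`.
#' Monotone decreasing in both OEF and CMRO2. Sub-zero tensions are
#' retained numerically (they classify as hypoxic); set `clamp_zero` to
#' floor at 0 as done in rendered maps.
#'
#' @param oef oxygen extraction fraction in (0, 2).
#' @param cmro2 umol/100g/min.
#' @param c constants from [physioConstants()].
#' @param clamp_zero floor the result at 0 mmHg.
#' @return PO2 in mmHg (vectorized); `NA` for OEF outside (0, 2).
#' @examples
#' computePo2(1, 0)  # p50 = 27 mmHg
#' @export
computePo2 <- function(oef, cmro2, c = physioConstants(), clamp_zero = FALSE) {
  po2 <- c$p50_mmhg * (2 / oef - 1)^(1 / c$hill_h) - cmro2 / c$l_conduct
  po2[!is.finite(po2) | oef <= 0 | oef >= 2] <- NA
  if (clamp_zero) po2 <- pmax(po2, 0)
  po2
}
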