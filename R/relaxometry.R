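# Voxelwise transverse relaxometry (R2*, R2) and diffusion (ADC).

#' Monoexponential relaxation fit
#'
#' Least-squares estimate of `S(TE) = S0 exp(-rate TE)` from a multi-echo
#' decay. The default estimator is a log-linear fit weighted by the squared
#' signal, which restores near maximum-likelihood behavior of the
#' log-transformed problem while staying deterministic and fast.
#' Non-positive signals are dropped before fitting; if fewer than three
#' usable echoes remain the voxel is flagged invalid (no exception).
#'
#' @param echo_times_s echo times (s).
#' @param signals measured signals, same length.
#' @param weighted use squared-signal weights (default TRUE).
#' @return list with `rate` (1/s), `s0`, `rsq` in `[0,1]`, and `valid`.
#'   Invalid fits carry `rate = NA`.
#' @examples
#' te <- seq(0.005, 0.040, length.out = 8)
#' fitMonoexponential(te, 1000 * exp(-30 * te))$rate  # 30
#' @export
fitMonoexponential <- function(echo_times_s, signals, weighted = TRUE) {
  ok <- is.finite(signals) & signals > 0
  invalid <- list(rate = NA_real_, s0 = NA_real_, rsq = NA_real_, valid = FALSE)
  if (sum(ok) < 3L) return(invalid)
  te <- echo_times_s[ok]; y <- log(signals[ok])
  w <- if (weighted) signals[ok]^2 else rep(1, length(te))
  sw <- sum(w); mx <- sum(w * te) / sw; my <- sum(w * y) / sw
  sxx <- sum(w * (te - mx)^2)
  if (sxx <= 0) return(invalid)
  slope <- sum(w * (te - mx) * (y - my)) / sxx
  rate <- -slope
  s0 <- exp(my - slope * mx)
  ssr <- sum(w * (y - (my + slope * (te - mx)))^2)
  sst <- sum(w * (y - my)^2)
  rsq <- if (sst > 0) max(0, min(1, 1 - ssr / sst)) else 1
  list(rate = rate, s0 = s0, rsq = rsq, valid = TRUE)
}

#' Voxelwise relaxation-rate map from a multi-echo series
#'
#' Applies [fitMonoexponential()] to every voxel in the mask (vectorized
#' across voxels). Voxels with fewer than three positive echoes, or outside
#' the mask, are flagged invalid (`NA`).
#'
#' @param series an [EchoSeries].
#' @param mask optional [VolumeImage] or logical array on the same grid.
#' @param drop_first_echo discard the first echo before fitting. Used for
#'   spin-echo trains, where the first echo carries the dominant
#'   stimulated-echo bias; dropping it is the standard cheap surrogate for a
#'   full extended-phase-graph correction.
#' @param weighted squared-signal weighting (see [fitMonoexponential()]).
#' @param name,units metadata for the output map.
#' @return a [VolumeImage] rate map (1/s).
#' @export
mapRelaxation <- function(series, mask = NULL, drop_first_echo = FALSE,
                          weighted = TRUE, name = "rate", units = "1/s") {
  stopifnot(is(series, "EchoSeries"))
  dat <- series@data
  te <- series@echoTimes
  if (drop_first_echo) {
    dat <- dat[, , , -1, drop = FALSE]
    te <- te[-1]
  }
  d <- dim(dat)
  m <- .mask_array(mask, d[1:3], series)
  nvox <- prod(d[1:3]); ne <- d[4]
  sig <- matrix(dat, nvox, ne)                    # voxels x echoes
  sig[!m, ] <- NA
  sig[sig <= 0] <- NA
  usable <- rowSums(is.finite(sig)) >= 3L
  y <- log(sig)
  w <- if (weighted) sig^2 else (sig * 0 + 1)
  w[!is.finite(y)] <- 0; y[!is.finite(y)] <- 0
  teM <- matrix(te, nvox, ne, byrow = TRUE)
  sw <- rowSums(w)
  mx <- rowSums(w * teM) / sw
  my <- rowSums(w * y) / sw
  dx <- teM - mx
  sxx <- rowSums(w * dx^2)
  slope <- rowSums(w * dx * (y - my)) / sxx
  rate <- -slope
  rate[!usable | !is.finite(rate) | sxx <= 0] <- NA
  volumeImage(array(rate, d[1:3]), affine = series@affine,
              units = units, name = name)
}

#' Through-slice background-gradient correction for gradient-echo decays
#'
#' Macroscopic through-slice field gradients superimpose a sinc-shaped
#' attenuation on the monoexponential R2* decay:
#' `S_meas(TE) = S(TE) |sinc(gamma G dz TE / 2)|`. This divides each echo by
#' that factor, given the gradient (T/mm, scalar or per-voxel array). With a
#' zero gradient the series is returned unchanged; if no gradient is
#' supplied the correction is skipped with a warning (no-op fallback).
#' The factor is floored so the correction can never produce negative or
#' exploding signals.
#'
#' @param series an [EchoSeries] (gradient-echo).
#' @param slice_thickness_mm excited slice thickness dz in mm.
#' @param fieldmap_gradient through-slice gradient in T/mm (scalar or 3D
#'   array), or NULL.
#' @param min_factor floor for the attenuation factor (default 0.05).
#' @return corrected [EchoSeries].
#' @export
correctBackgroundGradient <- function(series, slice_thickness_mm = 4,
                                      fieldmap_gradient = NULL,
                                      min_factor = 0.05) {
  stopifnot(is(series, "EchoSeries"))
  if (is.null(fieldmap_gradient)) {
    warning("no field gradient available; background correction skipped")
    return(series)
  }
  gamma <- physioConstants()$gamma
  d <- dim(series@data)
  out <- series@data
  for (j in seq_len(d[4])) {
    x <- gamma * fieldmap_gradient * slice_thickness_mm *
      series@echoTimes[j] / 2
    fac <- abs(ifelse(x == 0, 1, sin(x) / x))
    fac <- pmax(fac, min_factor)
    out[, , , j] <- out[, , , j] / fac
  }
  echoSeries(out, series@echoTimes, series@affine)
}

#' Apparent diffusion coefficient from a two-point DWI measurement
#'
#' `ADC = -ln(S_b / S_0) / b`. Noise can push `S_b` above `S_0`; such
#' voxels are clamped to ADC = 0 rather than reported negative. Voxels with
#' non-positive signals are invalid (`NA`).
#'
#' @param s0 signal at b = 0.
#' @param s_b signal at b-value `b`.
#' @param b diffusion weighting in s/mm^2.
#' @return ADC in mm^2/s (vectorized).
#' @examples
#' computeAdc(1000, 1000 * exp(-1), 1000)  # 1e-3 mm^2/s
#' @export
computeAdc <- function(s0, s_b, b = 1000) {
  stopifnot(b > 0)
  ok <- is.finite(s0) & is.finite(s_b) & s0 > 0 & s_b > 0
  ratio <- ifelse(ok, s_b / s0, NA_real_)
  adc <- -log(ratio) / b
  pmax(adc, 0)
}

#' ADC map from a b = 0 / b = 1000 volume pair
#'
#' @param b0_vol,b_vol [VolumeImage]s of the unweighted and weighted
#'   acquisitions.
#' @param b b-value (s/mm^2).
#' @param mask optional mask.
#' @return [VolumeImage] in mm^2/s.
#' @export
mapAdc <- function(b0_vol, b_vol, b = 1000, mask = NULL) {
  stopifnot(.same_grid(b0_vol, b_vol))
  adc <- computeAdc(b0_vol@data, b_vol@data, b)
  m <- .mask_array(mask, dim(adc), b0_vol)
  adc[!m] <- NA
  volumeImage(adc, affine = b0_vol@affine, units = "mm^2/s", name = "adc")
}

# resolve a mask argument to a logical array
.mask_array <- function(mask, dims, like) {
  if (is.null(mask)) return(array(TRUE, dims))
  m <- if (is(mask, "VolumeImage")) mask@data else mask
  if (!identical(dim(m)[1:3], as.integer(dims)))
    stop("mask grid does not match the series grid")
  array(m > 0 & is.finite(m), dims)
}
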