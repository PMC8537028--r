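# Vascular architecture mapping: the vascular hysteresis loop (VHL),
# microvessel type indicator (MTI), Q_max, microvessel density (MVD) and
# vessel size index (VSI).

#' Build the vascular hysteresis loop from paired GE/SE bolus curves
#'
#' The VHL is the closed curve traced during bolus passage in the
#' `dR2_GE` versus `(dR2_SE)^(3/2)` plane. Points are taken in acquisition
#' time order over the common first-pass window and the loop is closed by
#' repeating the first point. Negative SE values are clamped to 0 before
#' the 3/2 power.
#'
#' During bolus passage the gradient-echo rate (sensitive to all vessel
#' calibers) and the spin-echo rate (sensitive to microvessels) follow each
#' other with a caliber-dependent temporal shift, which opens the loop; its
#' signed area is the MTI.
#'
#' @param ge_curve,se_curve [bolusCurve()]s, or plain numeric vectors on a
#'   common time grid (fitted, recirculation-free curves).
#' @param window optional index range (defaults to the full common grid).
#' @return object of class `vhl`: matrix of (x, y) points, closed.
#' @export
buildVhl <- function(ge_curve, se_curve, window = NULL) {
  ge <- if (inherits(ge_curve, "bolus_curve")) ge_curve$delta_r2 else ge_curve
  se <- if (inherits(se_curve, "bolus_curve")) se_curve$delta_r2 else se_curve
  stopifnot(length(ge) == length(se))
  if (is.null(window)) {
    window <- if (inherits(ge_curve, "bolus_curve") &&
                  !is.null(ge_curve$first_pass_window))
      ge_curve$first_pass_window else seq_along(ge)
  }
  if (length(window) < 4) stop("first-pass window shorter than 4 samples")
  x <- pmax(se[window], 0)^1.5
  y <- ge[window]
  pts <- cbind(x = c(x, x[1]), y = c(y, y[1]))
  structure(list(points = pts, closed = TRUE), class = "vhl")
}

#' Microvessel type indicator: signed area of the VHL
#'
#' The negative of the shoelace signed area, so that a loop traversed
#' clockwise (in standard x-right / y-up axes) gives a positive MTI. A
#' positive MTI is conventionally read as an arteriole-dominated
#' microvasculature and a negative MTI as capillary/venule-dominated
#' vasculature (strong neovascularization when strongly negative); the
#' sign-to-biology mapping is a label only. Units: s^-1 x s^-3/2 = s^-5/2.
#'
#' @param vhl a `vhl` from [buildVhl()].
#' @return MTI in s^-5/2 (0 for degenerate loops).
#' @examples
#' sq <- buildVhl(c(0, 1, 1, 0), c(0, 0, 1, 1)^(2/3))  # clockwise unit square
#' computeMti(sq)  # +1
#' @export
computeMti <- function(vhl) {
  stopifnot(inherits(vhl, "vhl"))
  p <- vhl$points
  n <- nrow(p)
  x <- p[, 1]; y <- p[, 2]
  shoelace <- 0.5 * sum(x[-n] * y[-1] - x[-1] * y[-n])
  -shoelace
}

#' Q_max: ratio of GE and SE first-pass peaks
#'
#' `Q_max = max[dR2_GE] / max[(dR2_SE)^(3/2)]`, the peak-based summary of
#' the VHL axes used by the microvessel density and vessel size models.
#' The `literal` switch reproduces an alternative form with the GE curve in
#' the denominator as well; it is off by default because it contradicts the
#' VHL axis definitions.
#'
#' @param ge_curve,se_curve curves ([bolusCurve()] or numeric), or scalar
#'   peak values.
#' @param literal use `max[(dR2_GE)^(3/2)]` in the denominator.
#' @return Q_max in s^(1/2); `NA` when the denominator peak is not positive.
#' @examples
#' computeQmax(10, 4)  # 10 / 4^1.5 = 1.25
#' @export
computeQmax <- function(ge_curve, se_curve, literal = FALSE) {
  pk <- function(x) {
    v <- if (inherits(x, "bolus_curve")) x$delta_r2 else x
    max(v, na.rm = TRUE)
  }
  ge_pk <- pk(ge_curve)
  den_pk <- if (literal) ge_pk else pk(se_curve)
  if (!is.finite(den_pk) || den_pk <= 0 || !is.finite(ge_pk)) return(NA_real_)
  ge_pk / den_pk^1.5
}

#' Microvessel density
#'
#' `MVD = Q_max^b (CBV / (2^4 pi^2 ADC Rbar^4))^(1/3)` with the mean vessel
#' lumen radius Rbar in mm, so MVD lands in mm^-2. The formula is
#' semi-empirical (exponent b = 1.6781); dimensional analysis is not exact
#' and the expression is implemented literally.
#'
#' @param qmax Q_max (s^1/2).
#' @param cbv blood-volume fraction.
#' @param adc apparent diffusion coefficient (mm^2/s).
#' @param c constants from [physioConstants()] (`mean_radius_mm`, `b_mvd`).
#' @return MVD in mm^-2 (vectorized); `NA` for non-positive inputs.
#' @export
computeMvd <- function(qmax, cbv, adc, c = physioConstants()) {
  out <- qmax^c$b_mvd *
    (cbv / (2^4 * pi^2 * adc * c$mean_radius_mm^4))^(1 / 3)
  out[!is.finite(out) | qmax <= 0 | cbv <= 0 | adc <= 0] <- NA
  out
}

#' Vessel size index
#'
#' `VSI = (CBV ADC b^3 / (2 pi Q_max^3))^(1/2)` in mm, reported in
#' micrometres. Like MVD, the expression is semi-empirical and implemented
#' literally.
#'
#' @inheritParams computeMvd
#' @param um return micrometres (default) instead of mm.
#' @return VSI (vectorized); `NA` for non-positive inputs.
#' @export
computeVsi <- function(qmax, cbv, adc, c = physioConstants(), um = TRUE) {
  out <- sqrt(cbv * adc * c$b_mvd^3 / (2 * pi * qmax^3))
  out[!is.finite(out) | qmax <= 0 | cbv <= 0 | adc <= 0] <- NA
  if (um) out * 1e3 else out
}
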