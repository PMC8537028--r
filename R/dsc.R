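# DSC-MRI perfusion: signal-to-relaxation conversion, gamma-variate bolus
# fitting, automatic AIF selection, leakage correction, and absolute
# CBV/CBF via truncated-SVD deconvolution.

#' Bolus curve container
#'
#' A per-voxel relaxation-rate time course with its baseline and
#' first-pass windows.
#'
#' @param times_s acquisition times (s).
#' @param delta_r2 relaxation-rate change (1/s), same length.
#' @param n_baseline number of pre-bolus points.
#' @param first_pass_window optional integer range; detected automatically
#'   by [fitGammaVariate()] when absent.
#' @return object of class `bolus_curve`.
#' @export
bolusCurve <- function(times_s, delta_r2, n_baseline,
                       first_pass_window = NULL) {
  stopifnot(length(times_s) == length(delta_r2), n_baseline >= 3)
  structure(list(times_s = times_s, delta_r2 = delta_r2,
                 baseline_window = seq_len(n_baseline),
                 first_pass_window = first_pass_window),
            class = "bolus_curve")
}

#' Convert DSC signal time courses to relaxation-rate changes
#'
#' `dR2(t) = -ln(S(t) / S_baseline) / TE`, with the baseline taken as the
#' mean over the pre-bolus window, so the baseline mean of dR2 is ~0 by
#' construction. Voxels with non-positive signals anywhere in the series
#' are invalid (`NA` curves).
#'
#' @param series a [DynamicSeries].
#' @param mask optional mask.
#' @return list with `times` (s), `dr2` (time x voxel matrix), `dims`,
#'   and `n_baseline`.
#' @export
signalToDeltaR2 <- function(series, mask = NULL) {
  stopifnot(is(series, "DynamicSeries"))
  d <- dim(series@data)
  nt <- d[4]; nvox <- prod(d[1:3])
  m <- .mask_array(mask, d[1:3], series)
  sig <- t(matrix(series@data, nvox, nt))          # time x voxel
  bad <- colSums(!is.finite(sig) | sig <= 0) > 0 | !as.vector(m)
  base <- colMeans(sig[seq_len(series@nBaseline), , drop = FALSE])
  dr2 <- -log(sweep(sig, 2, base, "/")) / series@teS
  dr2[, bad] <- NA
  list(times = (seq_len(nt) - 1) * series@trS, dr2 = dr2,
       dims = d[1:3], n_baseline = series@nBaseline)
}

#' Evaluate a gamma-variate function
#'
#' `K (t - t0)^alpha exp(-(t - t0)/beta)` for `t > t0`, 0 before arrival.
#'
#' @param t times (s).
#' @param k amplitude.
#' @param t0 bolus arrival time (s).
#' @param alpha shape (> 0).
#' @param beta scale (s, > 0).
#' @export
gammaVariate <- function(t, k, t0, alpha, beta) {
  dt <- pmax(t - t0, 0)
  k * dt^alpha * exp(-dt / beta)
}

# moving average smoothing of the columns of a time x voxel matrix
.movavg_mat <- function(x, w) {
  if (w <= 1) return(x)
  nt <- nrow(x)
  cs <- apply(rbind(0, x), 2, cumsum)
  half <- (w - 1) %/% 2
  lo <- pmax(seq_len(nt) - half, 1)
  hi <- pmin(seq_len(nt) + (w - 1 - half), nt)
  (cs[hi + 1, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1)
}

.invalid_gamma <- function(reason = "undetectable") {
  list(k = NA_real_, t0 = NA_real_, alpha = NA_real_, beta = NA_real_,
       fit_error = NA_real_, valid = FALSE, reason = reason,
       peak = NA_real_, peak_time = NA_real_, integral = NA_real_,
       window = integer())
}

#' Fit a gamma-variate to the first-pass bolus of a dR2 curve
#'
#' Deterministic two-stage estimator: the first-pass window is located on a
#' moving-average-smoothed copy of the curve (from the bolus foot to the
#' first local minimum after the peak, which removes recirculation); the
#' gamma-variate `K (t-t0)^alpha exp(-(t-t0)/beta)` is then fitted by a
#' squared-signal-weighted log-linear regression over a grid of candidate
#' arrival times t0, picking the candidate with the smallest residual on
#' the original scale. An optional Levenberg-Marquardt polish
#' (`refine = TRUE`) refines all four parameters.
#'
#' Detection guard: the smoothed first-pass peak must exceed `detection_k`
#' times the noise SD of the smoothed baseline; curves failing it (e.g.
#' flat curves) return an invalid-fit result, not an exception.
#'
#' @param curve a [bolusCurve()], or a numeric dR2 vector.
#' @param times_s,n_baseline required when `curve` is a plain vector.
#' @param detection_k peak-detection multiplier (default 5).
#' @param smooth moving-average window for detection (default 5 points).
#' @param refine nonlinear refinement via [minpack.lm::nlsLM].
#' @param window optional fixed first-pass index window (e.g. determined
#'   once from the global mean curve by [firstPassWindow()]); per-curve
#'   detection of the window is the fallback.
#' @param arrival_s optional prior bolus-arrival time constraining the t0
#'   search to arrival +/- 2.5 TR.
#' @return list with `k`, `t0`, `alpha`, `beta`, `fit_error` (RMS residual
#'   over the first-pass window), `valid`, and the derived `peak`
#'   (= K (alpha beta)^alpha e^-alpha), `peak_time` (= t0 + alpha beta) and
#'   `integral` (= K beta^(alpha+1) Gamma(alpha+1)).
#' @export
fitGammaVariate <- function(curve, times_s = NULL, n_baseline = NULL,
                            detection_k = 5, smooth = 5, refine = FALSE,
                            window = NULL, arrival_s = NULL) {
  if (inherits(curve, "bolus_curve")) {
    times_s <- curve$times_s
    n_baseline <- length(curve$baseline_window)
    if (is.null(window)) window <- curve$first_pass_window
    y <- curve$delta_r2
  } else y <- curve
  if (any(!is.finite(y))) return(.invalid_gamma("invalid curve"))
  tr <- times_s[2] - times_s[1]
  ys <- as.vector(.movavg_mat(matrix(y), smooth))
  bl <- seq_len(n_baseline)
  sigma_s <- stats::sd(ys[bl])
  post <- if (is.null(window)) (n_baseline + 1):length(y) else window
  pk <- post[which.max(ys[post])]
  if (!is.finite(sigma_s) || sigma_s == 0) sigma_s <- 1e-12
  if (ys[pk] <= detection_k * sigma_s && stats::sd(y[bl]) > 0)
    return(.invalid_gamma("no detectable first pass"))
  if (max(abs(y - mean(y))) < 1e-12)
    return(.invalid_gamma("flat curve"))
  win <- if (is.null(window)) .first_pass_window(ys, n_baseline, pk)
         else window
  fit <- .gamma_loglin(times_s, y, win, pk, tr, arrival_s)
  if (!fit$valid) return(fit)
  if (refine) fit <- .gamma_refine(times_s, y, win, fit)
  fit
}

#' Locate the first-pass window of a bolus curve
#'
#' From the last pre-bolus index to the first local minimum after the
#' peak, on a moving-average-smoothed copy of the curve. Applied to the
#' global (brain-mean) curve it yields the common window used for every
#' voxel of a series, which is how the pipeline calls it; bolus timing is
#' global up to small arrival shifts.
#'
#' @param dr2 dR2 curve (vector).
#' @param n_baseline pre-bolus points.
#' @param smooth moving-average window.
#' @return integer index range.
#' @export
firstPassWindow <- function(dr2, n_baseline, smooth = 5) {
  ys <- as.vector(.movavg_mat(matrix(dr2), smooth))
  post <- (n_baseline + 1):length(dr2)
  pk <- post[which.max(ys[post])]
  .first_pass_window(ys, n_baseline, pk)
}

# window from bolus foot to first local minimum after the peak
.first_pass_window <- function(ys, n_baseline, pk) {
  thr <- 0.05 * ys[pk]
  start <- pk
  while (start > n_baseline + 1 && ys[start - 1] > thr) start <- start - 1
  end <- pk
  nt <- length(ys)
  while (end < nt && !(ys[end + 1] > ys[end]) && ys[end] > thr) end <- end + 1
  start:end
}

.gamma_deriveds <- function(fit) {
  fit$peak <- fit$k * (fit$alpha * fit$beta)^fit$alpha * exp(-fit$alpha)
  fit$peak_time <- fit$t0 + fit$alpha * fit$beta
  fit$integral <- fit$k * fit$beta^(fit$alpha + 1) * gamma(fit$alpha + 1)
  fit
}

.gamma_loglin <- function(t, y, win, pk, tr, arrival_s = NULL) {
  ymax <- y[pk]
  cand <- if (is.null(arrival_s)) {
    seq(t[win[1]] - 1.5 * tr, t[pk] - 0.75 * tr, by = tr / 8)
  } else {
    seq(arrival_s - 2.5 * tr, min(arrival_s + 2.5 * tr, t[pk] - 0.75 * tr),
        by = tr / 8)
  }
  cand <- cand[cand >= 0]
  best <- NULL; best_rss <- Inf
  for (t0 in cand) {
    # fit only points above 15% of the peak: near-zero samples carry no
    # shape information and, under noise, survive the positivity filter
    # asymmetrically, which would bias the fitted tail upward
    use <- win[t[win] > t0 + 1e-9 & y[win] > 0.15 * ymax]
    if (length(use) < 4) next
    dt <- t[use] - t0
    X <- cbind(1, log(dt), dt)
    yy <- log(y[use])
    sw <- y[use]                                  # sqrt of y^2 weights
    cf <- tryCatch(stats::.lm.fit(X * sw, yy * sw)$coefficients,
                   error = function(e) NULL)
    if (is.null(cf) || any(!is.finite(cf))) next
    alpha <- cf[2]; beta <- -1 / cf[3]; K <- exp(cf[1])
    if (!is.finite(alpha) || !is.finite(beta) || alpha <= 0 || beta <= 0) next
    resid <- y[win] - gammaVariate(t[win], K, t0, alpha, beta)
    rss <- sum(resid^2)
    if (rss < best_rss) {
      best_rss <- rss
      best <- list(k = K, t0 = t0, alpha = alpha, beta = beta)
    }
  }
  if (is.null(best)) return(.invalid_gamma("log-linear fit failed"))
  best$fit_error <- sqrt(best_rss / length(win))
  best$valid <- TRUE; best$reason <- ""
  best$window <- win
  .gamma_deriveds(best)
}

.gamma_refine <- function(t, y, win, fit) {
  df <- data.frame(t = t[win], y = y[win])
  nl <- tryCatch(
    minpack.lm::nlsLM(
      y ~ K * pmax(t - t0, 0)^a * exp(-pmax(t - t0, 0) / b),
      data = df,
      start = list(K = fit$k, t0 = fit$t0, a = fit$alpha, b = fit$beta),
      lower = c(0, 0, 1e-3, 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(nl)) {
    fit$refined <- FALSE
    return(fit)
  }
  cf <- stats::coef(nl)
  out <- list(k = unname(cf["K"]), t0 = unname(cf["t0"]),
              alpha = unname(cf["a"]), beta = unname(cf["b"]),
              fit_error = sqrt(mean(stats::resid(nl)^2)),
              valid = TRUE, reason = "", refined = TRUE, window = win)
  .gamma_deriveds(out)
}

#' Automatic arterial input function selection
#'
#' Scores every candidate voxel by high peak, early arrival and narrow
#' first-pass width (score = peak / (width x arrival delay)), keeps voxels
#' whose peak exceeds the median tissue peak and whose arrival is not later
#' than the median arrival, and averages the raw curves of the `top_n`
#' best. Ties are broken by the lowest linear voxel index, so the result is
#' deterministic given the input.
#'
#' @param dr2 time x voxel matrix of dR2 curves (from [signalToDeltaR2()]).
#' @param times_s acquisition times.
#' @param n_baseline pre-bolus points.
#' @param mask optional logical vector of candidate voxels.
#' @param top_n curves averaged (default 10).
#' @param min_candidates required candidate count (default 100).
#' @return list with `curve` (a [bolusCurve()]), `voxels` (linear indices
#'   of the source voxels) and `score`.
#' @export
selectAif <- function(dr2, times_s, n_baseline, mask = NULL, top_n = 10,
                      min_candidates = 100) {
  nvox <- ncol(dr2)
  cand <- if (is.null(mask)) rep(TRUE, nvox) else as.vector(mask) > 0
  cand <- cand & colSums(!is.finite(dr2)) == 0
  if (sum(cand) < min_candidates)
    stop("fewer than ", min_candidates, " AIF candidate voxels; ",
         "supply an AIF explicitly via the config (aif_mode = 'supplied')")
  ys <- .movavg_mat(dr2, 3)
  post <- (n_baseline + 1):nrow(dr2)
  sub <- ys[post, , drop = FALSE]
  pkv <- apply(sub, 2, max)
  pki <- apply(sub, 2, which.max)
  arr <- integer(nvox); wid <- integer(nvox)
  for (v in which(cand)) {
    thr <- 0.1 * pkv[v]
    a <- 1
    while (a < pki[v] && sub[a, v] < thr) a <- a + 1
    arr[v] <- a
    wid[v] <- sum(sub[, v] > 0.5 * pkv[v])
  }
  med_pk <- stats::median(pkv[cand])
  med_arr <- stats::median(arr[cand])
  ok <- cand & pkv >= med_pk & arr <= med_arr & wid >= 1
  if (!any(ok))
    stop("no qualifying AIF voxels; supply an AIF explicitly via the config")
  score <- ifelse(ok, pkv / (pmax(wid, 1) * arr), -Inf)
  ord <- order(-score, seq_len(nvox))
  sel <- ord[seq_len(min(top_n, sum(ok)))]
  aif <- rowMeans(dr2[, sel, drop = FALSE])
  list(curve = bolusCurve(times_s, aif, n_baseline),
       voxels = sel, score = score[sel])
}

#' Boxerman-style leakage correction of a dR2 curve
#'
#' Regresses the voxel curve on the whole-brain (non-enhancing) reference
#' curve and its cumulative integral; the coefficient on the integral
#' captures contrast-agent extravasation, and that component is subtracted.
#' A rank-deficient regression (e.g. a degenerate reference) passes the
#' curve through unchanged with a flag.
#'
#' @param curve a [bolusCurve()] or numeric dR2 vector.
#' @param reference reference dR2 vector from non-enhancing brain.
#' @param times_s required when `curve` is a plain vector.
#' @return list with `dr2` (corrected curve), `k1`, `k2` (leakage
#'   coefficient, 1/s), and `flag`.
#' @export
correctLeakage <- function(curve, reference, times_s = NULL) {
  if (inherits(curve, "bolus_curve")) {
    times_s <- curve$times_s
    y <- curve$delta_r2
  } else y <- curve
  tr <- times_s[2] - times_s[1]
  cum <- cumsum(reference) * tr
  X <- cbind(reference, cum)
  if (qr(X)$rank < 2 || any(!is.finite(y)))
    return(list(dr2 = y, k1 = NA_real_, k2 = NA_real_, flag = "passthrough"))
  cf <- stats::.lm.fit(X, y)$coefficients
  list(dr2 = y - cf[2] * cum, k1 = cf[1], k2 = cf[2], flag = "ok")
}

#' Absolute CBV and CBF from tissue and arterial dR2 curves
#'
#' CBV is the tissue-to-arterial concentration integral ratio scaled by the
#' hematocrit factor `k_H` (blood-volume fraction); CBF is the maximum of
#' the residue function recovered by delay-insensitive (block-circulant)
#' truncated-SVD deconvolution of the tissue curve against the AIF, scaled
#' by `k_H / rho` and converted to mL/100g/min. Singular values below
#' `svd_threshold` times the largest are discarded.
#'
#' @param tissue_dr2 numeric vector or time x voxel matrix of (fitted,
#'   recirculation-free) tissue curves.
#' @param aif_dr2 arterial curve on the same time grid.
#' @param tr_s sampling interval (s).
#' @param c constants from [physioConstants()].
#' @param svd_threshold TSVD cut as a fraction of the largest singular
#'   value.
#' @return list with `cbv` (fraction), `cbf` (mL/100g/min); voxels with an
#'   invalid curve get `NA`. Errors if the AIF integral is zero.
#' @export
computeCbvCbf <- function(tissue_dr2, aif_dr2, tr_s, c = physioConstants(),
                          svd_threshold = 0.10) {
  if (is.vector(tissue_dr2)) tissue_dr2 <- matrix(tissue_dr2)
  nt <- nrow(tissue_dr2)
  stopifnot(length(aif_dr2) == nt)
  aif_int <- sum(aif_dr2) * tr_s
  if (abs(aif_int) < 1e-12) stop("AIF integral is zero")
  sc <- dscScaling(c)
  bad <- colSums(!is.finite(tissue_dr2)) > 0
  tis <- tissue_dr2; tis[, bad] <- 0
  cbv <- sc$k_h * colSums(tis) * tr_s / aif_int
  # block-circulant deconvolution, shared SVD across voxels
  L <- 2L * nt
  ap <- c(aif_dr2, rep(0, L - nt))
  A <- tr_s * sapply(seq_len(L), function(j) ap[((seq_len(L) - j) %% L) + 1])
  sv <- svd(A)
  dinv <- ifelse(sv$d >= svd_threshold * max(sv$d), 1 / sv$d, 0)
  Cpad <- rbind(tis, matrix(0, L - nt, ncol(tis)))
  resid_fn <- sv$v %*% (dinv * (t(sv$u) %*% Cpad))
  fmax <- apply(resid_fn, 2, max)
  cbf <- sc$k_h / sc$rho * fmax * 6000             # 1/s -> mL/100g/min
  cbv[bad] <- NA; cbf[bad] <- NA
  list(cbv = as.vector(cbv), cbf = as.vector(cbf))
}
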