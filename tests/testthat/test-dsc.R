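# DSC: signal conversion, gamma-variate fitting, AIF selection, leakage
# correction, CBV/CBF deconvolution.

.mk_series <- function(dr2_curve, te = 0.022, tr = 1.74, n_base = 10,
                       s0 = 1000, dims = c(3, 3, 1)) {
  nt <- length(dr2_curve)
  arr <- array(0, c(dims, nt))
  for (j in seq_len(nt)) arr[, , , j] <- s0 * exp(-dr2_curve[j] * te)
  dynamicSeries(arr, tr, te, n_base)
}

test_that("signal-to-dR2 conversion follows the log transform", {
  nt <- 60
  curve <- rep(0, nt)
  ser <- .mk_series(curve)
  out <- signalToDeltaR2(ser)
  expect_equal(max(abs(out$dr2)), 0, tolerance = 1e-12)
  # a drop to S/e at the peak gives dR2 = 1/TE
  curve[30] <- 1 / 0.022
  out2 <- signalToDeltaR2(.mk_series(curve))
  expect_equal(out2$dr2[30, 1], 1 / 0.022, tolerance = 1e-9)
  expect_equal(out2$dr2[30, 1], 45.45, tolerance = 1e-2)
  # doubling TE halves dR2 for the same signal drop
  sig <- 1000 * exp(-curve * 0.022)
  arr1 <- array(rep(sig, each = 1), c(1, 1, 1, nt))
  d1 <- signalToDeltaR2(dynamicSeries(arr1, 1.74, 0.022, 10))
  d2 <- signalToDeltaR2(dynamicSeries(arr1, 1.74, 0.044, 10))
  expect_equal(d1$dr2[30, 1], 2 * d2$dr2[30, 1], tolerance = 1e-9)
  # baseline mean is ~0 by construction
  expect_equal(mean(out2$dr2[1:10, 1]), 0, tolerance = 1e-12)
})

test_that("gamma-variate fit self-inverts on noiseless input", {
  t <- (0:59) * 1.74
  y <- gammaVariate(t, k = 2.5, t0 = 20, alpha = 3, beta = 1.5)
  fit <- fitGammaVariate(y, times_s = t, n_baseline = 10, refine = TRUE)
  expect_true(fit$valid)
  expect_equal(fit$t0, 20, tolerance = 1e-6)
  expect_equal(fit$alpha, 3, tolerance = 1e-6)
  expect_equal(fit$beta, 1.5, tolerance = 1e-6)
  expect_equal(fit$k, 2.5, tolerance = 1e-5)
  # analytic mode: peak time = t0 + alpha beta
  expect_equal(fit$peak_time, 20 + 3 * 1.5, tolerance = 1e-6)
  expect_equal(fit$peak, max(gammaVariate(seq(20, 40, 1e-3), 2.5, 20, 3, 1.5)),
               tolerance = 1e-6)
  # analytic integral matches numeric quadrature
  expect_equal(fit$integral,
               integrate(gammaVariate, 20, Inf, k = 2.5, t0 = 20,
                         alpha = 3, beta = 1.5)$value, tolerance = 1e-6)
})

test_that("flat or undetectable curves give invalid fits, not errors", {
  t <- (0:59) * 1.74
  flat <- fitGammaVariate(rep(1, 60), times_s = t, n_baseline = 10)
  expect_false(flat$valid)
  set.seed(1)
  noise_only <- fitGammaVariate(rnorm(60, 0, 1), times_s = t,
                                n_baseline = 10)
  expect_false(noise_only$valid)
})

test_that("AIF selection finds the designated arterial voxels", {
  t <- (0:59) * 1.74
  nvox <- 120
  tissue <- gammaVariate(t, 0.4, 24, 3, 1.5)
  artery <- gammaVariate(t, 1.6, 22, 3, 1.5)    # 3x peak, earlier arrival
  dr2 <- matrix(rep(tissue, nvox), ncol = nvox)
  art_vox <- c(5, 17, 42)
  dr2[, art_vox] <- artery
  sel <- selectAif(dr2, t, 10, top_n = 3)
  expect_setequal(sel$voxels, art_vox)
  expect_equal(sel$curve$delta_r2, artery, tolerance = 1e-12)
  # ties broken by lowest linear index: all-identical candidates
  dr2_same <- matrix(rep(artery, nvox), ncol = nvox)
  sel2 <- selectAif(dr2_same, t, 10, top_n = 4)
  expect_equal(sel2$voxels, 1:4)
  expect_error(selectAif(dr2[, 1:50], t, 10), "100")
})

test_that("leakage correction removes a constructed leakage term", {
  t <- (0:59) * 1.74
  ref <- gammaVariate(t, 0.5, 22, 3, 1.5)
  lambda <- 0.07
  leaky <- ref + lambda * cumsum(ref) * 1.74
  out <- correctLeakage(leaky, ref, t)
  expect_equal(out$k2, lambda, tolerance = 1e-9)
  expect_equal(out$dr2, ref, tolerance = 1e-9)
  # zero-leakage curve passes through unchanged
  clean <- correctLeakage(ref, ref, t)
  expect_equal(clean$dr2, ref, tolerance = 1e-9)
  expect_equal(clean$k2, 0, tolerance = 1e-9)
  # baseline mean stays at zero
  expect_equal(mean(out$dr2[1:10]), 0, tolerance = 1e-9)
  # degenerate reference: passthrough with flag
  deg <- correctLeakage(leaky, rep(0, 60), t)
  expect_equal(deg$flag, "passthrough")
  expect_equal(deg$dr2, leaky)
})

test_that("CBV and CBF scale as the theory says", {
  t <- (0:59) * 1.74; tr <- 1.74
  aif <- gammaVariate(t, 2, 22, 3, 1.5)
  kh <- dscScaling()$k_h
  # tissue identical to AIF -> CBV = k_H
  res <- computeCbvCbf(aif, aif, tr)
  expect_equal(res$cbv, kh, tolerance = 1e-9)
  # halving the AIF doubles both CBV and CBF
  tissue <- 0.05 * gammaVariate(t, 2, 24, 3.2, 1.7)
  full <- computeCbvCbf(tissue, aif, tr)
  half <- computeCbvCbf(tissue, aif / 2, tr)
  expect_equal(half$cbv, 2 * full$cbv, tolerance = 1e-9)
  expect_equal(half$cbf, 2 * full$cbf, tolerance = 1e-6)
  # shifting AIF and tissue together changes nothing (delay-insensitive)
  sh <- 4
  shift <- function(x, m) c(rep(0, m), x[1:(length(x) - m)])
  shifted <- computeCbvCbf(shift(tissue, sh), shift(aif, sh), tr)
  expect_equal(shifted$cbv, full$cbv, tolerance = 1e-9)
  expect_equal(shifted$cbf, full$cbf, tolerance = 1e-6)
  expect_error(computeCbvCbf(tissue, aif * 0, tr), "AIF integral")
})

test_that("deconvolution recovers flow for box and exponential residues", {
  t <- (0:59) * 1.74; tr <- 1.74
  aif <- gammaVariate(t, 2, 22, 3, 1.5)
  sc <- dscScaling()
  f_frac <- 8e-3                           # 1/s apparent flow
  cbf_true <- f_frac * 6000 * sc$k_h / sc$rho
  # box residue of duration MTT: discrete max equals f exactly
  mtt <- 8
  r_box <- as.numeric(t <= mtt)
  conv <- function(a, r) tr * stats::convolve(a, rev(r),
                                              type = "open")[1:length(a)]
  tis_box <- f_frac * conv(aif, r_box)
  # noiseless box residue: a light truncation recovers the flow exactly
  rec <- computeCbvCbf(tis_box, aif, tr, svd_threshold = 0.02)
  expect_equal(rec$cbf, cbf_true, tolerance = 0.05)
  # independent small-instance oracle: brute-force enumeration of
  # (flow, duration) against the forward model
  grid_f <- seq(0.5, 1.5, by = 0.01) * f_frac
  grid_m <- seq(4, 12, by = 0.5)
  rss <- outer(grid_f, grid_m, Vectorize(function(f, m)
    sum((f * conv(aif, as.numeric(t <= m)) - tis_box)^2)))
  best <- which(rss == min(rss), arr.ind = TRUE)[1, ]
  expect_equal(grid_f[best[1]], f_frac, tolerance = 1e-9)
  expect_equal(min(rss), 0, tolerance = 1e-12)
  # durations are identified up to the sampling grid
  expect_equal(as.numeric(t <= grid_m[best[2]]), r_box)
  # exponential residue with long MTT at 60-point sampling
  r_exp <- exp(-t / 12)
  tis_exp <- f_frac * conv(aif, r_exp)
  rec2 <- computeCbvCbf(tis_exp, aif, tr, svd_threshold = 0.05)
  expect_equal(rec2$cbf, cbf_true, tolerance = 0.1)
})
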