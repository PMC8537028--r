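# Synthetic phantom: forward models, determinism, presets, noise scaling.

test_that("forward multi-echo decays invert to the prescribed rates", {
  ph <- generatePhantom(make_small_phantom("oxphos", dim = c(8, 8, 2)))
  pre <- defaultCompartmentPresets()
  r2s <- mapRelaxation(ph$bundle$gre)
  r2 <- mapRelaxation(ph$bundle$mese, drop_first_echo = TRUE)
  roi <- imgData(ph$bundle$roi) > 0
  # noiseless inversion of the model recovers rates to < 0.1% relative
  expect_lt(max(abs(imgData(r2s)[roi] / pre["oxphos", "r2star"] - 1)), 1e-3)
  expect_lt(max(abs(imgData(r2)[roi] / pre["oxphos", "r2"] - 1)), 1e-3)
  # DWI pair encodes the preset ADC exactly
  adc <- mapAdc(ph$bundle$dwi_b0, ph$bundle$dwi_b)
  expect_equal(unique(round(imgData(adc)[roi], 9)), pre["oxphos", "adc"],
               tolerance = 1e-6)
})

test_that("phantom generation is deterministic given the seed", {
  p1 <- generatePhantom(make_small_phantom(snr = 40, seed = 11,
                                           dim = c(8, 8, 2)))
  p2 <- generatePhantom(make_small_phantom(snr = 40, seed = 11,
                                           dim = c(8, 8, 2)))
  expect_identical(imgData(p1$bundle$dsc_ge), imgData(p2$bundle$dsc_ge))
  expect_identical(imgData(p1$bundle$gre), imgData(p2$bundle$gre))
  p3 <- generatePhantom(make_small_phantom(snr = 40, seed = 12,
                                           dim = c(8, 8, 2)))
  expect_false(identical(imgData(p1$bundle$dsc_ge),
                         imgData(p3$bundle$dsc_ge)))
})

test_that("truth labels tile the ROI with the prescribed shares", {
  spec <- phantomSpec(dim = c(24, 24, 6), snr = Inf)
  ph <- generatePhantom(spec)
  roi <- imgData(ph$bundle$roi) > 0
  lab <- imgData(ph$truth$labels)
  expect_true(all(lab[roi] %in% 1:5))
  expect_true(all(lab[!roi] == 0))
  shares <- as.vector(table(lab[roi])) / sum(roi)
  expect_equal(shares, c(0.4, 0.2, 0.2, 0.1, 0.1), tolerance = 0.02)
})

test_that("forward DSC obeys the lag/direction hysteresis contract", {
  t <- (0:59) * 1.74
  # zero lag: the SE curve is a pure rescaling of the GE curve, so the
  # VHL degenerates to a retraced line; the area vanishes in the
  # continuum limit (assessed on the fine forward grid)
  fw0 <- forwardDsc(0.05, 60, lag_s = 0, qmax_target = 1, times_s = t)
  expect_equal(computeMti(buildVhl(fw0$fine$ge, fw0$fine$se)), 0,
               tolerance = 0.01)
  # clockwise direction gives positive MTI; flipping the direction flips
  # the sign, with the magnitude preserved to first order in the lag
  fwp <- forwardDsc(0.05, 60, lag_s = 2, loop_direction = 1,
                    qmax_target = 1, times_s = t)
  fwm <- forwardDsc(0.05, 60, lag_s = 2, loop_direction = -1,
                    qmax_target = 1, times_s = t)
  mti_p <- computeMti(buildVhl(fwp$fine$ge, fwp$fine$se))
  mti_m <- computeMti(buildVhl(fwm$fine$ge, fwm$fine$se))
  expect_gt(mti_p, 5)
  expect_lt(mti_m, -5)
  expect_equal(mti_p, -mti_m, tolerance = 0.25)
  # |loop area| grows monotonically with lag (oracle: shoelace on the
  # generated curves)
  areas <- sapply(c(0.5, 1, 2, 3), function(lg) {
    fw <- forwardDsc(0.05, 60, lag_s = lg, loop_direction = 1,
                     qmax_target = 1, times_s = t)
    abs(oracle_shoelace(pmax(fw$se_dr2, 0)^1.5, fw$ge_dr2))
  })
  expect_true(all(diff(areas) > 0))
  # the prescribed Q_max is attained
  fw <- forwardDsc(0.06, 50, lag_s = 0, qmax_target = 0.7, times_s = t)
  expect_equal(max(fw$ge_dr2) / max(fw$se_dr2)^1.5, 0.7, tolerance = 0.02)
  # guards
  expect_error(forwardDsc(0, 60), "cbv")
  expect_error(forwardDsc(0.05, 60, lag_s = 50, qmax_target = 1,
                          times_s = t), "bolus width")
})

test_that("compartment presets realize their classification cells", {
  pre <- defaultCompartmentPresets()
  cns <- physioConstants()
  rules <- classificationRules()
  for (cl in c("glycolysis", "oxphos", "necrosis", "hypoxia_nv",
               "hypoxia_nonv")) {
    p <- pre[cl, ]
    # closed-form chain on the ground-truth values
    oef <- p$oef
    cmro2 <- computeCmro2(oef, p$cbf, cns)
    po2 <- computePo2(oef, cmro2, cns)
    mvd <- computeMvd(p$qmax_target, p$cbv, p$adc, cns)
    mti_proxy <- ifelse(p$lag_s > 0, 30 * p$loop_direction, 0)
    lab <- classifyVoxel(cmro2, 100 * oef, mti_proxy, mvd, po2, rules)
    expect_equal(unname(lab), rules$label[rules$class == cl],
                 info = paste("preset", cl))
    expect_gte(p$r2star, p$r2)
  }
  # the worked examples of the preset table
  nec <- pre["necrosis", ]
  expect_lt(computeCmro2(nec$oef, nec$cbf, cns), 130)
  expect_gt(100 * nec$oef, 75)
  gly <- pre["glycolysis", ]
  expect_lt(100 * gly$oef, 20)
  expect_gt(computeMvd(gly$qmax_target, gly$cbv, gly$adc, cns), 250)
})

test_that("hypoxic presets yield PO2 below 10 mmHg through the Hill model", {
  # direct-arithmetic oracle, e.g. OEF 45% at CMRO2 250
  expect_lt(oracle_po2(0.45, 250), 10)
  pre <- defaultCompartmentPresets()
  for (cl in c("hypoxia_nv", "hypoxia_nonv")) {
    p <- pre[cl, ]
    cmro2 <- 8.68 * p$cbf * p$oef
    expect_lt(oracle_po2(p$oef, cmro2), 10)
  }
})

test_that("estimator dispersion decreases with SNR", {
  # R2* estimates across seeds at SNR 20 / 50 / 100
  te <- seq(0.005, 0.040, length.out = 8)
  spread <- sapply(c(20, 50, 100), function(snr) {
    set.seed(100 + snr)
    ests <- replicate(60, {
      s <- 1000 * exp(-18 * te)
      n1 <- rnorm(8, 0, 1000 / snr); n2 <- rnorm(8, 0, 1000 / snr)
      fitMonoexponential(te, sqrt((s + n1)^2 + n2^2))$rate
    })
    sd(ests)
  })
  expect_true(all(diff(spread) < 0))
})
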