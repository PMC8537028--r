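# Five-class TME classification: band rules, NV rule, precedence,
# exhaustive audit, map construction.

test_that("PO2 bands use the published limits with closed normoxia", {
  expect_equal(classifyPo2Band(9.99), "hypoxic")
  expect_equal(classifyPo2Band(10.0), "normoxic")
  expect_equal(classifyPo2Band(60.0), "normoxic")
  expect_equal(classifyPo2Band(60.01), "hyperoxic")
  expect_true(is.na(classifyPo2Band(NA)))
})

test_that("neovascularization rule is |MTI| and/or MVD", {
  expect_equal(classifyNeovascularization(0, 400), "no_NV")
  expect_equal(classifyNeovascularization(-20, 400), "functional_NV")
  expect_equal(classifyNeovascularization(20, 100), "no_NV")
  expect_equal(classifyNeovascularization(5.0, 400), "no_NV")   # boundary
  expect_equal(classifyNeovascularization(-5.1, 251), "functional_NV")
})

test_that("voxel classification matches the published criteria table", {
  # very low CMRO2 + very high OEF -> necrosis regardless of PO2
  expect_equal(classifyVoxel(50, 90, 0, 100, 30), 3L)
  # normal CMRO2, high OEF, no NV, hypoxic -> hypoxia without NV
  expect_equal(classifyVoxel(100, 60, 0, 100, 5), 5L)
  # low OEF + strong NV + hyperoxic -> glycolysis; PO2 from the Hill model
  po2 <- oracle_po2(0.10, 50)
  expect_gt(po2, 60)
  expect_equal(classifyVoxel(50, 10, -20, 400, po2), 1L)
  # high CMRO2 + NV + hypoxic -> hypoxia with NV
  expect_equal(classifyVoxel(200, 40, -15, 400, 5), 4L)
  # normoxic + NV + high CMRO2 -> OxPhos
  expect_equal(classifyVoxel(120, 30, -15, 400, 30), 2L)
  # no match -> unclassified
  expect_equal(classifyVoxel(60, 60, 0, 100, 30), 0L)
  # invalid biomarker -> 0
  expect_equal(classifyVoxel(NA, 30, -15, 400, 30), 0L)
})

test_that("necrosis precedence resolves the overlap with hypoxia-no-NV", {
  # this cell satisfies both necrosis and hypoxia-without-NV
  expect_equal(classifyVoxel(100, 80, 0, 100, 5), 3L)
})

test_that("classification is local, deterministic and vectorized", {
  set.seed(5)
  n <- 500
  cm <- runif(n, 0, 400); oef <- runif(n, 0, 110)
  mti <- runif(n, -30, 30); mvd <- runif(n, 0, 600)
  po2 <- computePo2(oef / 100, cm)
  lab1 <- classifyVoxel(cm, oef, mti, mvd, po2)
  lab2 <- classifyVoxel(cm, oef, mti, mvd, po2)
  expect_identical(lab1, lab2)
  # locality: each label equals the scalar call on that voxel alone
  idx <- sample(n, 25)
  for (i in idx)
    expect_identical(lab1[i], classifyVoxel(cm[i], oef[i], mti[i], mvd[i],
                                            po2[i]))
})

test_that("exhaustive audit reports gaps and stable overlap resolution", {
  a1 <- auditRules()
  a2 <- auditRules()
  expect_identical(a1, a2)
  # the rule table leaves genuine gaps (e.g. CMRO2 < 80 with OEF 50-75)
  expect_gt(a1$frac_none, 0)
  # overlaps exist (necrosis vs hypoxia-no-NV) but are rare
  expect_gt(a1$frac_multi, 0)
  expect_lt(a1$frac_multi, 0.05)
})

test_that("PO2-band consistency holds on classified phantoms", {
  set.seed(8)
  n <- 2000
  cm <- runif(n, 0, 400); oef <- runif(n, 0, 110)
  mti <- runif(n, -30, 30); mvd <- runif(n, 0, 600)
  po2 <- computePo2(oef / 100, cm)
  lab <- classifyVoxel(cm, oef, mti, mvd, po2)
  band <- classifyPo2Band(po2)
  expect_true(all(band[lab == 1] == "hyperoxic"))
  expect_true(all(band[lab == 2] == "normoxic"))
  expect_true(all(band[lab %in% 4:5] == "hypoxic"))
})

test_that("buildTmeMap labels only inside the ROI and exports the scatter", {
  d <- c(6, 6, 2)
  mk <- function(x) volumeImage(array(x, d), units = "x", name = "m")
  bio <- list(oef = mk(0.10), cmro2 = mk(50), mti = mk(-20), mvd = mk(400),
              po2 = mk(oracle_po2(0.10, 50)))
  roi <- array(FALSE, d); roi[2:4, 2:4, 1] <- TRUE
  map <- buildTmeMap(bio, roi)
  lab <- imgData(tmeLabels(map))
  expect_true(all(lab[roi] == 1L))
  expect_true(all(lab[!roi] == 0L))
  sc <- oefCmro2Scatter(map)
  expect_equal(nrow(sc), sum(roi))
  expect_equal(unique(sc$label), 1L)
  expect_equal(unique(sc$oef_percent), 10)
  # empty ROI -> empty map and zero summary
  map0 <- buildTmeMap(bio, array(FALSE, d))
  expect_true(all(imgData(tmeLabels(map0)) == 0L))
  # grid mismatch is an error
  bad <- bio; bad$mvd <- volumeImage(array(400, c(3, 3, 1)), units = "x")
  expect_error(buildTmeMap(bad, roi), "common grid")
})

test_that("median filter is exact on constant regions and fills holes", {
  d <- c(8, 8, 2)
  roi <- array(FALSE, d); roi[2:7, 2:7, ] <- TRUE
  x <- array(1000, d)          # background value outside ROI
  x[roi] <- 42
  x[4, 4, 1] <- NA             # failed-fit voxel
  v <- volumeImage(x, units = "x")
  f <- medianFilterRoi(v, roi)
  expect_equal(imgData(f)[4, 4, 1], 42)          # hole filled from ROI
  expect_true(all(imgData(f)[roi] == 42))        # exact on constant region
  expect_true(all(imgData(f)[!roi] == 1000))     # untouched outside
})
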