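# Homogeneity gate, Welch ANOVA, Tukey and Games-Howell post hoc tests.

test_that("ROI summary reproduces aggregation identities", {
  d <- c(10, 10, 1)
  lab <- array(0L, d)
  lab[1:37] <- 1L; lab[38:54] <- 2L          # 37 glycolysis + 17 oxphos
  lab[55:69] <- 4L; lab[70:78] <- 5L         # 15 + 9 hypoxia
  lab[79:100] <- 3L                          # 22 necrosis
  map <- new("TMEMap",
             labels = volumeImage(lab + 0, units = "label"),
             legend = data.frame(label = 0:5, class = letters[1:6],
                                 color = "x"))
  s <- summarizeRoi(map, array(TRUE, d))
  p <- compartmentPercent(s)
  expect_equal(sum(p), 100)
  expect_equal(unname(derivedPercent(s)["vital_tumor"]), 54)
  expect_equal(unname(derivedPercent(s)["total_hypoxia"]), 24)
  expect_equal(unname(derivedPercent(s)["active_tumor"]), 54)
  # all-unclassified ROI
  map0 <- new("TMEMap", labels = volumeImage(array(0, d), units = "label"),
              legend = map@legend)
  s0 <- summarizeRoi(map0, array(TRUE, d))
  expect_equal(unname(compartmentPercent(s0)["unclassified"]), 100)
  expect_equal(sum(compartmentPercent(s0)[1:5]), 0)
  expect_error(summarizeRoi(map, array(FALSE, d)), "empty ROI")
})

test_that("summary percentages are permutation invariant", {
  set.seed(2)
  d <- c(6, 6, 3)
  lab <- array(sample(0:5, prod(d), replace = TRUE), d)
  leg <- data.frame(label = 0:5, class = letters[1:6], color = "x")
  m1 <- new("TMEMap", labels = volumeImage(lab + 0, units = "l"),
            legend = leg)
  perm <- array(lab[sample(prod(d))], d)
  m2 <- new("TMEMap", labels = volumeImage(perm + 0, units = "l"),
            legend = leg)
  expect_equal(compartmentPercent(summarizeRoi(m1, array(TRUE, d))),
               compartmentPercent(summarizeRoi(m2, array(TRUE, d))))
})

test_that("Levene gate matches a brute-force Brown-Forsythe oracle", {
  set.seed(10)
  x <- c(rnorm(12, 0, 1), rnorm(15, 0, 4), rnorm(9, 1, 2))
  g <- rep(c("a", "b", "c"), c(12, 15, 9))
  ours <- varianceHomogeneity(x, g)
  orc <- oracle_levene_bf(x, g)
  expect_equal(ours$statistic, orc$F, tolerance = 1e-10)
  expect_equal(ours$p, orc$p, tolerance = 1e-10)
  # identical value sets -> statistic 0
  same <- varianceHomogeneity(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  # degenerate constant groups -> p = 1 with flag
  deg <- varianceHomogeneity(rep(c(1, 2), each = 5), rep(c("a", "b"), each = 5))
  expect_equal(deg$p, 1)
  expect_equal(deg$flag, "degenerate")
})

test_that("Levene rejects strongly unequal variances (power property)", {
  set.seed(77)
  hits <- 0
  for (r in 1:200) {
    x <- c(rnorm(50, 0, 1), rnorm(50, 0, 10))
    g <- rep(c("a", "b"), each = 50)
    if (varianceHomogeneity(x, g)$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.95)
})

test_that("Welch ANOVA equals the step-by-step formula oracle", {
  # fixed small dataset with unequal variances and sizes
  x <- c(27.1, 22.5, 24.4, 26.0, 25.3, 23.8,
         14.2, 18.9, 16.5, 17.1,
         19.9, 22.4, 21.0, 20.2, 23.1)
  g <- rep(c("g1", "g2", "g3"), c(6, 4, 5))
  ours <- welchAnova(x, g)
  orc <- oracle_welch(x, g)
  expect_equal(ours$statistic, orc$F, tolerance = 1e-10)
  expect_equal(unname(ours$df[2]), orc$df2, tolerance = 1e-10)
  expect_equal(ours$p, orc$p, tolerance = 1e-10)
})

test_that("Games-Howell equals the step-by-step formula oracle", {
  set.seed(4)
  x <- c(rnorm(20, 10, 1), rnorm(12, 14, 5), rnorm(25, 11, 2),
         rnorm(8, 9, 3))
  g <- rep(c("a", "b", "c", "d"), c(20, 12, 25, 8))
  ours <- gamesHowell(x, g)
  orc <- oracle_games_howell(x, g)
  expect_equal(ours$p, orc$p, tolerance = 1e-10)
  # four identical groups -> no pairwise significance
  xx <- rep(c(1, 2, 3, 4, 5), 4)
  gg <- rep(c("a", "b", "c", "d"), each = 5)
  expect_true(all(gamesHowell(xx, gg)$p > 0.999))
})

test_that("Tukey and Games-Howell converge for equal n and variance", {
  # with equal group sizes and spreads the two procedures share the same
  # limiting reference; at finite n they differ only through the pooled
  # vs per-pair degrees of freedom, which vanishes as n grows
  set.seed(6)
  base <- rnorm(300)
  x <- c(base, base + 0.25, base - 0.12)     # identical spread per group
  g <- rep(c("a", "b", "c"), each = 300)
  th <- tukeyPairwise(x, g)
  gh <- gamesHowell(x, g)
  m <- merge(th, gh, by = c("group1", "group2"))
  expect_lt(max(abs(m$p.x - m$p.y)), 1e-3)
  expect_equal(m$diff.x, m$diff.y, tolerance = 1e-10)
})

test_that("compareGroups gates between Tukey and Games-Howell", {
  set.seed(9)
  # heteroscedastic: Welch + Games-Howell
  tab1 <- data.frame(group = rep(c("a", "b", "c"), each = 30),
                     m = c(rnorm(30, 0, 1), rnorm(30, 0, 8), rnorm(30, 2, 1)))
  r1 <- compareGroups(tab1, "m")
  expect_equal(r1$method, "welch_games_howell")
  # homoscedastic: classical ANOVA + Tukey
  tab2 <- data.frame(group = rep(c("a", "b", "c"), each = 30),
                     m = rnorm(90, 0, 2))
  r2 <- compareGroups(tab2, "m")
  expect_equal(r2$method, "anova_tukey")
  expect_gt(r2$omnibus$p, 0.001)
  # four identical groups -> omnibus p ~ 1, no pairwise significance
  tab3 <- data.frame(group = rep(c("a", "b", "c", "d"), each = 5),
                     m = rep(c(1, 2, 3, 4, 5), 4))
  r3 <- compareGroups(tab3, "m")
  expect_gt(r3$omnibus$p, 0.99)
  expect_true(all(r3$pairwise$p > 0.99))
})

test_that("the full gate+test procedure controls type-I error", {
  set.seed(123)
  rejections <- 0
  nrep <- 400
  for (r in 1:nrep) {
    tab <- data.frame(group = rep(c("a", "b", "c", "d"), each = 15),
                      m = rnorm(60))
    if (compareGroups(tab, "m")$omnibus$p < 0.05) rejections <- rejections + 1
  }
  expect_lte(rejections / nrep, 0.07)
})

test_that("group means feed the radar-chart vectors", {
  tab <- data.frame(group = rep(c("a", "b"), each = 2),
                    glycolysis = c(30, 50, 60, 70), oxphos = c(10, 20, 20, 30))
  gm <- groupMeans(tab)
  expect_equal(gm$glycolysis, c(40, 65))
  expect_equal(gm$oxphos, c(15, 25))
})
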