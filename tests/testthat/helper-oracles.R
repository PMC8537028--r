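# Independent brute-force oracles used across the suite. These deliberately
# re-derive quantities from first principles (direct arithmetic, shoelace,
# textbook formulas) and never call the implementation they check.

# shoelace signed area of a closed polygon (positive = counterclockwise)
oracle_shoelace <- function(x, y) {
  n <- length(x)
  0.5 * sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
}

# qBOLD scaling constant from first principles
oracle_k <- function(b0 = 3.0) {
  (4 / 3) * pi * 2.67502e8 * 0.264e-6 * (0.42 * 0.85) * b0
}

# Hill-model oxygen tension, direct arithmetic
oracle_po2 <- function(oef, cmro2, p50 = 27, h = 2.7, L = 4.4) {
  p50 * (2 / oef - 1)^(1 / h) - cmro2 / L
}

# microvessel density, direct arithmetic
oracle_mvd <- function(qmax, cbv, adc, rbar = 3.0e-3, b = 1.6781) {
  qmax^b * (cbv / (2^4 * pi^2 * adc * rbar^4))^(1 / 3)
}

# vessel size index in mm, direct arithmetic
oracle_vsi <- function(qmax, cbv, adc, b = 1.6781) {
  sqrt(cbv * adc * b^3 / (2 * pi * qmax^3))
}

# Welch's one-way ANOVA computed step by step from the textbook formulas
oracle_welch <- function(values, groups) {
  g <- factor(groups)
  ni <- tapply(values, g, length)
  mi <- tapply(values, g, mean)
  vi <- tapply(values, g, var)
  wi <- ni / vi
  k <- nlevels(g)
  mw <- sum(wi * mi) / sum(wi)
  A <- sum(wi * (mi - mw)^2) / (k - 1)
  lambda <- sum((1 - wi / sum(wi))^2 / (ni - 1)) / (k^2 - 1)
  Fstat <- A / (1 + 2 * lambda * (k - 2))
  df2 <- 1 / (3 * lambda)
  p <- pf(Fstat, k - 1, df2, lower.tail = FALSE)
  list(F = Fstat, df1 = k - 1, df2 = df2, p = p)
}

# Games-Howell pairwise p-values computed step by step
oracle_games_howell <- function(values, groups) {
  g <- factor(groups)
  lev <- levels(g)
  k <- length(lev)
  out <- NULL
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    xi <- values[g == lev[i]]; xj <- values[g == lev[j]]
    se2 <- var(xi) / length(xi) + var(xj) / length(xj)
    df <- se2^2 / ((var(xi) / length(xi))^2 / (length(xi) - 1) +
                   (var(xj) / length(xj))^2 / (length(xj) - 1))
    tt <- (mean(xi) - mean(xj)) / sqrt(se2)
    p <- ptukey(sqrt(2) * abs(tt), nmeans = k, df = df, lower.tail = FALSE)
    out <- rbind(out, data.frame(group1 = lev[i], group2 = lev[j], p = p))
  }
  out
}

# Brown-Forsythe statistic as a one-way ANOVA on absolute deviations from
# the group median
oracle_levene_bf <- function(values, groups) {
  g <- factor(groups)
  z <- abs(values - ave(values, g, FUN = median))
  an <- summary(aov(z ~ g))[[1]]
  list(F = an$`F value`[1], p = an$`Pr(>F)`[1])
}

# small single-region acquisition bundle for fast end-to-end tests
make_small_phantom <- function(class = "glycolysis", snr = Inf, seed = 1,
                               dim = c(16, 16, 4)) {
  cls <- c("glycolysis", "oxphos", "necrosis", "hypoxia_nv", "hypoxia_nonv")
  shares <- stats::setNames(as.numeric(cls == class), cls)
  phantomSpec(dim = dim, shares = shares, snr = snr, seed = seed)
}
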