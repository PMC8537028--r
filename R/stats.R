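# Group-level statistics across tumor entities: homogeneity-of-variance
# gate, one-way/Welch ANOVA, Tukey HSD and Games-Howell post hoc tests.

#' Levene/Brown-Forsythe homogeneity-of-variance test
#'
#' Median-centered (Brown-Forsythe) by default, mean-centered on request;
#' the standard F reference distribution. Degenerate input (all groups
#' constant) reports p = 1 with a flag instead of failing.
#'
#' @param values numeric observations.
#' @param groups group labels, same length.
#' @param center `"median"` (robust, default) or `"mean"`.
#' @return list with `statistic`, `df`, `p`, `flag`.
#' @export
varianceHomogeneity <- function(values, groups, center = c("median", "mean")) {
  center <- match.arg(center)
  g <- factor(groups)
  stopifnot(nlevels(g) >= 2, all(table(g) >= 2))
  if (all(tapply(values, g, stats::var) < .Machine$double.eps))
    return(list(statistic = 0, df = c(nlevels(g) - 1,
                                      length(values) - nlevels(g)),
                p = 1, flag = "degenerate"))
  lt <- car::leveneTest(values, g,
                        center = if (center == "median") stats::median
                                 else mean)
  list(statistic = lt$`F value`[1], df = c(lt$Df[1], lt$Df[2]),
       p = lt$`Pr(>F)`[1], flag = "ok")
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' Asymptotically valid under unequal group variances; the reference is
#' the F distribution with Welch-Satterthwaite denominator degrees of
#' freedom.
#'
#' @param values,groups observations and group labels.
#' @return list with `statistic` (F), `df` (num, denom), `p`.
#' @export
welchAnova <- function(values, groups) {
  g <- factor(groups)
  ow <- stats::oneway.test(values ~ g, var.equal = FALSE)
  list(statistic = unname(ow$statistic), df = unname(ow$parameter),
       p = unname(ow$p.value))
}

#' Games-Howell pairwise comparisons
#'
#' Post hoc procedure for unequal variances and group sizes: for each pair
#' the standard error is `sqrt(s_i^2/n_i + s_j^2/n_j)`, the degrees of
#' freedom are per-pair Welch-Satterthwaite, and the p-value refers
#' `q = sqrt(2) |t|` to the studentized range distribution with the number
#' of groups as the number of means. Implemented from the defining
#' formulas (the studentized-range CDF comes from [stats::ptukey()]).
#'
#' @param values,groups observations and group labels.
#' @param conf_level confidence level for the interval half-widths.
#' @return data.frame: group1, group2, diff, se, df, t, p, conf_lo,
#'   conf_hi.
#' @export
gamesHowell <- function(values, groups, conf_level = 0.95) {
  g <- factor(groups)
  lev <- levels(g)
  k <- length(lev)
  stopifnot(k >= 2)
  m <- tapply(values, g, mean)
  v <- tapply(values, g, stats::var)
  n <- tapply(values, g, length)
  out <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se2 <- v[i] / n[i] + v[j] / n[j]
    se <- sqrt(se2)
    df <- se2^2 / ((v[i] / n[i])^2 / (n[i] - 1) +
                   (v[j] / n[j])^2 / (n[j] - 1))
    diff <- m[i] - m[j]
    tt <- diff / se
    p <- stats::ptukey(sqrt(2) * abs(tt), nmeans = k, df = df,
                       lower.tail = FALSE)
    qcrit <- stats::qtukey(conf_level, nmeans = k, df = df)
    half <- qcrit * se / sqrt(2)
    out[[length(out) + 1]] <- data.frame(
      group1 = lev[i], group2 = lev[j], diff = unname(diff),
      se = unname(se), df = unname(df), t = unname(tt), p = unname(p),
      conf_lo = unname(diff - half), conf_hi = unname(diff + half),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Tukey HSD pairwise comparisons
#'
#' Classical equal-variance post hoc test via [stats::TukeyHSD()],
#' reshaped to the same schema as [gamesHowell()].
#'
#' @param values,groups observations and group labels.
#' @param conf_level confidence level.
#' @return data.frame: group1, group2, diff, p, conf_lo, conf_hi.
#' @export
tukeyPairwise <- function(values, groups, conf_level = 0.95) {
  g <- factor(groups)
  fit <- stats::aov(values ~ g)
  th <- stats::TukeyHSD(fit, conf.level = conf_level)$g
  nm <- strsplit(rownames(th), "-", fixed = TRUE)
  data.frame(group1 = vapply(nm, `[`, "", 2),
             group2 = vapply(nm, `[`, "", 1),
             diff = -th[, "diff"], p = th[, "p adj"],
             conf_lo = -th[, "upr"], conf_hi = -th[, "lwr"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare a compartment metric between tumor-entity groups
#'
#' The full decision procedure: a Levene (Brown-Forsythe) gate at
#' `alpha_gate` chooses between classical one-way ANOVA with Tukey HSD
#' (variances homogeneous) and Welch's ANOVA with Games-Howell post hoc
#' tests (variances unequal). All intermediate statistics are returned.
#'
#' @param table data.frame with one row per subject: a `group` column and
#'   numeric metric columns (e.g. the output of [summarizeRoi()] per
#'   subject plus a group label).
#' @param metric name of the column to compare.
#' @param alpha_gate significance level of the homogeneity gate (0.05).
#' @param center centering of the Levene gate.
#' @return list with `method` ("anova_tukey" or "welch_games_howell"),
#'   `levene`, `omnibus` (statistic, df, p) and `pairwise` (data.frame).
#' @export
compareGroups <- function(table, metric, alpha_gate = 0.05,
                          center = "median") {
  stopifnot(metric %in% names(table), "group" %in% names(table))
  x <- table[[metric]]
  g <- factor(table$group)
  stopifnot(nlevels(g) >= 2)
  lev <- varianceHomogeneity(x, g, center = center)
  if (lev$p >= alpha_gate) {
    fit <- stats::aov(x ~ g)
    an <- summary(fit)[[1]]
    omnibus <- list(statistic = an$`F value`[1],
                    df = c(an$Df[1], an$Df[2]), p = an$`Pr(>F)`[1])
    pw <- tukeyPairwise(x, g)
    method <- "anova_tukey"
  } else {
    omnibus <- welchAnova(x, g)
    pw <- gamesHowell(x, g)
    method <- "welch_games_howell"
  }
  list(method = method, levene = lev, omnibus = omnibus, pairwise = pw)
}

#' Per-group mean compartment vectors
#'
#' The per-entity mean of each compartment percentage — the numbers a
#' radar chart of group TME profiles plots.
#'
#' @param table subject-level table with `group` and metric columns.
#' @param metrics columns to average.
#' @return data.frame, one row per group.
#' @export
groupMeans <- function(table,
                       metrics = c("glycolysis", "oxphos", "necrosis",
                                   "hypoxia_nv", "hypoxia_nonv")) {
  metrics <- intersect(metrics, names(table))
  agg <- stats::aggregate(table[metrics], by = list(group = table$group),
                          mean)
  agg
}
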