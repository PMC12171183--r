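#' Assemble a cohort table of per-participant spatial metrics
#'
#' @param df data frame with columns `participant_id`, `age_group`
#'   (`"young"`/`"older"`), `sex` (`"male"`/`"female"`), `muscle`,
#'   `metric_name`, `value`.
#' @return The validated data frame, classed `cohort_table`.
#' @export
cohort_table <- function(df) {
  need <- c("participant_id", "age_group", "sex", "muscle", "metric_name", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("cohort table missing columns: ", paste(miss, collapse = ", "))
  if (!all(df$age_group %in% c("young", "older")))
    stop("age_group must be 'young' or 'older'")
  if (!all(df$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  key <- paste(df$participant_id, df$muscle, df$metric_name)
  if (anyDuplicated(key))
    stop("duplicate (participant, muscle, metric) rows")
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Normality and variance-homogeneity checks
#'
#' Shapiro-Wilk per group and Levene's test (median-centred,
#' Brown-Forsythe variant) across groups. The parametric branch is taken
#' iff every Shapiro-Wilk p and the Levene p exceed 0.05; any group with
#' fewer than 3 observations forces the nonparametric branch.
#'
#' @param values numeric vector.
#' @param groups grouping factor/vector of the same length.
#' @param alpha significance level for branch selection.
#' @return List: `shapiro_p` (named per group), `levene_p`, `branch`
#'   (`"parametric"` or `"nonparametric"`), `forced` (logical).
#' @export
assumption_checks <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  sp <- split(values, groups)
  if (any(vapply(sp, function(v) sd(v) == 0, logical(1))))
    stop("degenerate input: constant values within a group")
  if (any(lengths(sp) < 3L)) {
    return(list(shapiro_p = setNames(rep(NA_real_, length(sp)), names(sp)),
                levene_p = NA_real_, branch = "nonparametric", forced = TRUE))
  }
  shapiro_p <- vapply(sp, function(v) shapiro.test(v)$p.value, numeric(1))
  lev <- car::leveneTest(values ~ groups, center = median)
  levene_p <- lev[["Pr(>F)"]][1]
  branch <- if (all(shapiro_p > alpha) && levene_p > alpha)
    "parametric" else "nonparametric"
  list(shapiro_p = shapiro_p, levene_p = levene_p, branch = branch,
       forced = FALSE)
}

#' Two-way (age x sex) ANOVA with Type-II sums of squares
#'
#' Type-II decomposition (via `car::Anova`) is used because the design is
#' unbalanced and no interaction is assumed a priori; on balanced data it
#' coincides with the classical decomposition.
#'
#' @param tab a [cohort_table()] (optionally already filtered to one muscle).
#' @param metric metric name to analyse.
#' @param muscle optional muscle to filter on.
#' @return Data frame with rows `age_group`, `sex`, `age_group:sex` and
#'   columns `F`, `p`, `df`.
#' @export
two_way_anova <- function(tab, metric, muscle = NULL) {
  d <- tab[tab$metric_name == metric, , drop = FALSE]
  if (!is.null(muscle)) d <- d[d$muscle == muscle, , drop = FALSE]
  d$age_group <- factor(d$age_group, levels = c("young", "older"))
  d$sex <- factor(d$sex, levels = c("male", "female"))
  cells <- table(d$age_group, d$sex)
  if (any(cells == 0)) stop("empty age x sex cell")
  mod <- lm(value ~ age_group * sex, data = d)
  a <- car::Anova(mod, type = 2)
  eff <- c("age_group", "sex", "age_group:sex")
  data.frame(effect = eff,
             F = a[eff, "F value"],
             p = a[eff, "Pr(>F)"],
             df = a[eff, "Df"],
             row.names = NULL)
}

#' Hedges' g effect size
#'
#' Bias-corrected standardised mean difference
#' `g = J * (mean_a - mean_b) / s_pooled`, with
#' `s_pooled = sqrt(((n_a-1) s_a^2 + (n_b-1) s_b^2) / (n_a + n_b - 2))`
#' and small-sample correction `J = 1 - 3 / (4 (n_a + n_b) - 9)`.
#'
#' @param group_a,group_b numeric vectors with >= 2 values each.
#' @return Hedges' g (signed: positive when `group_a` has the larger mean).
#' @export
hedges_g <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L) stop("need at least 2 values per group")
  sp2 <- ((na - 1) * var(group_a) + (nb - 1) * var(group_b)) / (na + nb - 2)
  if (sp2 == 0) stop("zero pooled variance")
  J <- 1 - 3 / (4 * (na + nb) - 9)
  J * (mean(group_a) - mean(group_b)) / sqrt(sp2)
}

#' Dunn's pairwise rank test
#'
#' All pairwise z statistics on pooled ranks with tie correction; p-values
#' are two-sided with the requested multiplicity adjustment (Bonferroni by
#' default, as in the nonparametric post-hoc branch).
#'
#' @param values numeric vector.
#' @param groups grouping vector.
#' @param p_adjust method passed to [p.adjust()].
#' @return Data frame with `group1`, `group2`, `z`, `p`, `p_adj`.
#' @export
dunn_test <- function(values, groups, p_adjust = "bonferroni") {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ns <- tabulate(groups)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  lev <- levels(groups)
  cmb <- utils::combn(seq_along(lev), 2)
  z <- p <- numeric(ncol(cmb))
  for (k in seq_len(ncol(cmb))) {
    i <- cmb[1, k]; j <- cmb[2, k]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ns[i] + 1 / ns[j]))
    z[k] <- (rbar[i] - rbar[j]) / se
    p[k] <- 2 * pnorm(-abs(z[k]))
  }
  data.frame(group1 = lev[cmb[1, ]], group2 = lev[cmb[2, ]],
             z = z, p = p, p_adj = p.adjust(p, method = p_adjust))
}

#' Post-hoc pairwise comparisons among the four age x sex groups
#'
#' Parametric branch: Tukey's HSD on the one-way layout over the four
#' age x sex cells. Nonparametric branch: Dunn's test with Bonferroni
#' correction. Hedges' g is attached to every pair.
#'
#' @param tab a [cohort_table()].
#' @param metric metric name.
#' @param branch `"parametric"` or `"nonparametric"`.
#' @param muscle optional muscle filter.
#' @return Data frame: `group1`, `group2`, `mean_diff`, `p_adj`, `hedges_g`.
#' @export
posthoc <- function(tab, metric, branch = c("parametric", "nonparametric"),
                    muscle = NULL) {
  branch <- match.arg(branch)
  d <- tab[tab$metric_name == metric, , drop = FALSE]
  if (!is.null(muscle)) d <- d[d$muscle == muscle, , drop = FALSE]
  grp <- factor(paste(d$age_group, d$sex, sep = "_"))
  if (branch == "parametric") {
    tk <- TukeyHSD(aov(d$value ~ grp))$grp
    pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
    out <- data.frame(group1 = vapply(pairs, `[`, "", 1),
                      group2 = vapply(pairs, `[`, "", 2),
                      mean_diff = tk[, "diff"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  } else {
    dn <- dunn_test(d$value, grp, p_adjust = "bonferroni")
    means <- tapply(d$value, grp, mean)
    out <- data.frame(group1 = dn$group1, group2 = dn$group2,
                      mean_diff = means[dn$group1] - means[dn$group2],
                      p_adj = pmin(dn$p_adj, 1), row.names = NULL)
  }
  out$hedges_g <- mapply(function(a, b)
    hedges_g(d$value[grp == a], d$value[grp == b]), out$group1, out$group2)
  rownames(out) <- NULL
  out
}

#' Full statistical report for one metric
#'
#' Per muscle: assumption checks over the four age x sex groups; then the
#' parametric branch (two-way ANOVA + Tukey HSD) or the nonparametric
#' branch (Friedman across muscles within participants, Kruskal-Wallis
#' across groups, Dunn-Bonferroni post hoc), each with Hedges' g.
#'
#' @param tab a [cohort_table()].
#' @param metric metric name.
#' @param alpha significance level (0.05 by default).
#' @return Object of class `stat_report`: a list per muscle with elements
#'   `assumptions`, `branch`, `anova` (or `kruskal`/`friedman`), `posthoc`.
#' @export
stat_report <- function(tab, metric, alpha = 0.05) {
  d <- tab[tab$metric_name == metric, , drop = FALSE]
  if (nrow(d) == 0L) stop("metric not found: ", metric)
  muscles <- unique(d$muscle)
  per_muscle <- lapply(muscles, function(m) {
    dm <- d[d$muscle == m, , drop = FALSE]
    grp <- paste(dm$age_group, dm$sex, sep = "_")
    chk <- assumption_checks(dm$value, grp, alpha)
    if (chk$branch == "parametric") {
      list(assumptions = chk, branch = "parametric",
           anova = two_way_anova(tab, metric, muscle = m),
           posthoc = posthoc(tab, metric, "parametric", muscle = m))
    } else {
      fr <- tryCatch({
        wide <- tapply(d$value, list(d$participant_id, d$muscle), mean)
        wide <- wide[complete.cases(wide), , drop = FALSE]
        if (ncol(wide) >= 2L && nrow(wide) >= 2L)
          friedman.test(as.matrix(wide))$p.value else NA_real_
      }, error = function(e) NA_real_)
      kw <- kruskal.test(dm$value, factor(grp))
      list(assumptions = chk, branch = "nonparametric",
           friedman_p = fr, kruskal_p = kw$p.value,
           posthoc = posthoc(tab, metric, "nonparametric", muscle = m))
    }
  })
  names(per_muscle) <- muscles
  structure(list(metric = metric, alpha = alpha, muscles = per_muscle),
            class = "stat_report")
}

#' @export
print.stat_report <- function(x, ...) {
  cat("<stat_report> metric:", x$metric, "\n")
  for (m in names(x$muscles)) {
    r <- x$muscles[[m]]
    cat("  ", m, " [", r$branch, "]", sep = "")
    if (r$branch == "parametric") {
      a <- r$anova
      cat(sprintf("  age F=%.2f p=%.3g; sex F=%.2f p=%.3g; int F=%.2f p=%.3g\n",
                  a$F[1], a$p[1], a$F[2], a$p[2], a$F[3], a$p[3]))
    } else {
      cat(sprintf("  Kruskal-Wallis p=%.3g\n", r$kruskal_p))
    }
  }
  invisible(x)
}
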