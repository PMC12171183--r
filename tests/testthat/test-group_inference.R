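test_that("Hedges' g matches hand-derived values and is antisymmetric", {
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  expect_equal(hedges_g(a, b), -0.8, tolerance = 1e-12)  # d = -1, J = 0.8
  expect_equal(hedges_g(b, a), 0.8, tolerance = 1e-12)
  expect_equal(hedges_g(a, a), 0)
  expect_error(hedges_g(c(1, 1), c(1, 1)), "zero pooled variance")
  expect_error(hedges_g(1, b), "at least 2")
  # J -> 1 as n grows: g approaches Cohen's d
  set.seed(41)
  x <- rnorm(1e4); y <- rnorm(1e4) + 0.5
  d <- (mean(x) - mean(y)) /
    sqrt(((1e4 - 1) * var(x) + (1e4 - 1) * var(y)) / (2e4 - 2))
  expect_equal(hedges_g(x, y), d, tolerance = 1e-4)
})

test_that("two-way ANOVA F matches a from-scratch sums-of-squares oracle", {
  # balanced 2x2 with n = 3 per cell: Type II equals the classical
  # decomposition, computed here by hand
  d <- data.frame(
    participant_id = 1:12,
    age_group = rep(c("young", "older"), each = 6),
    sex = rep(rep(c("male", "female"), each = 3), 2),
    muscle = "MG", metric_name = "m",
    value = c(5.1, 4.9, 5.3, 6.0, 6.2, 5.8, 7.1, 7.0, 7.4, 8.2, 7.9, 8.3))
  tab <- cohort_table(d)
  res <- two_way_anova(tab, "m")

  y <- d$value
  A <- factor(d$age_group); B <- factor(d$sex)
  gm <- mean(y)
  ssA <- sum(tapply(y, A, function(v) length(v) * (mean(v) - gm)^2))
  ssB <- sum(tapply(y, B, function(v) length(v) * (mean(v) - gm)^2))
  cellm <- tapply(y, list(A, B), mean)
  ssCells <- 3 * sum((cellm - gm)^2)
  ssAB <- ssCells - ssA - ssB
  ssE <- sum((y - ave(y, A, B))^2)
  fA <- (ssA / 1) / (ssE / 8)
  fB <- (ssB / 1) / (ssE / 8)
  fAB <- (ssAB / 1) / (ssE / 8)
  expect_equal(res$F[res$effect == "age_group"], fA, tolerance = 1e-10)
  expect_equal(res$F[res$effect == "sex"], fB, tolerance = 1e-10)
  expect_equal(res$F[res$effect == "age_group:sex"], fAB, tolerance = 1e-10)
})

test_that("ANOVA null case: equal group means give large p", {
  set.seed(42)
  d <- data.frame(
    participant_id = 1:40,
    age_group = rep(c("young", "older"), each = 20),
    sex = rep(c("male", "female"), 20),
    muscle = "MG", metric_name = "m",
    value = rnorm(40, 5, 1))
  res <- two_way_anova(cohort_table(d), "m")
  expect_true(all(res$p > 0.01))
  # planted 2-sigma age shift is detected, sex stays null
  d2 <- d
  d2$value <- d2$value + ifelse(d2$age_group == "older", 2, 0)
  res2 <- two_way_anova(cohort_table(d2), "m")
  expect_lt(res2$p[res2$effect == "age_group"], 0.001)
  expect_gt(res2$p[res2$effect == "sex"], 0.05)
})

test_that("assumption checks gate the branch on Shapiro and Levene", {
  set.seed(43)
  g <- rep(letters[1:4], each = 15)
  v <- rnorm(60)
  chk <- assumption_checks(v, g)
  expect_named(chk$shapiro_p, letters[1:4])
  expect_true(chk$branch %in% c("parametric", "nonparametric"))
  expect_identical(chk$branch,
                   if (all(chk$shapiro_p > 0.05) && chk$levene_p > 0.05)
                     "parametric" else "nonparametric")
  # a 10x-variance group trips Levene
  v2 <- v; v2[g == "d"] <- rnorm(15, 0, 10)
  chk2 <- assumption_checks(v2, g)
  expect_lt(chk2$levene_p, 0.05)
  expect_identical(chk2$branch, "nonparametric")
  # undersized group forces the nonparametric branch
  chk3 <- assumption_checks(c(v, 1, 2), c(g, "e", "e"))
  expect_identical(chk3$branch, "nonparametric")
  expect_true(chk3$forced)
  expect_error(assumption_checks(c(rep(1, 5), rnorm(5)),
                                 rep(c("a", "b"), each = 5)), "degenerate")
})

test_that("test calibration: null p-values exceed alpha at the nominal rate", {
  set.seed(44)
  shap <- lev <- logical(0)
  for (s in 1:60) {
    v <- rnorm(48)
    g <- rep(letters[1:4], each = 12)
    chk <- assumption_checks(v, g)
    shap <- c(shap, chk$shapiro_p > 0.05)
    lev <- c(lev, chk$levene_p > 0.05)
  }
  # binomial tolerance around 0.95 (240 and 60 draws)
  expect_gt(mean(shap), 0.89)
  expect_gt(mean(lev), 0.85)
})

test_that("Dunn test applies the 6-fold Bonferroni factor", {
  set.seed(45)
  v <- rnorm(40)
  g <- rep(c("ym", "yf", "om", "of"), each = 10)
  dn <- dunn_test(v, g)
  expect_equal(nrow(dn), 6)
  expect_equal(dn$p_adj, pmin(dn$p * 6, 1), tolerance = 1e-12)
  # z statistic against a manual oracle for one pair
  r <- rank(v)
  N <- 40
  ties <- table(v)
  tc <- sum(ties^3 - ties) / (12 * (N - 1))
  i <- "of"; j <- "om"
  z_oracle <- (mean(r[g == i]) - mean(r[g == j])) /
    sqrt((N * (N + 1) / 12 - tc) * (1 / 10 + 1 / 10))
  row <- dn[dn$group1 == i & dn$group2 == j, ]
  if (nrow(row) == 0) {
    row <- dn[dn$group1 == j & dn$group2 == i, ]
    z_oracle <- -z_oracle
  }
  expect_equal(row$z, z_oracle, tolerance = 1e-12)
})

test_that("post hoc flags only comparisons involving a shifted group", {
  set.seed(46)
  hits <- 0L
  for (s in 1:10) {
    d <- data.frame(
      participant_id = 1:48,
      age_group = rep(c("young", "older"), each = 24),
      sex = rep(rep(c("male", "female"), each = 12), 2),
      muscle = "MG", metric_name = "m",
      value = rnorm(48))
    shift <- d$age_group == "older" & d$sex == "male"
    d$value[shift] <- d$value[shift] + 3
    tab <- cohort_table(d)
    ph <- posthoc(tab, "m", "parametric")
    target <- grepl("older_male", ph$group1) | grepl("older_male", ph$group2)
    if (all(ph$p_adj[target] < 0.05) && all(ph$p_adj[!target] > 0.05))
      hits <- hits + 1L
  }
  expect_gte(hits, 8L)
  # identical groups: adjusted p near 1
  d0 <- data.frame(participant_id = 1:20,
                   age_group = rep(c("young", "older"), each = 10),
                   sex = rep(c("male", "female"), 10),
                   muscle = "MG", metric_name = "m",
                   value = rep(c(1.0, 1.1, 0.9, 1.05, 0.95), 4))
  ph0 <- posthoc(cohort_table(d0), "m", "nonparametric")
  expect_true(all(ph0$p_adj > 0.9))
})

test_that("stat_report takes the branch its assumption checks dictate", {
  set.seed(47)
  d <- data.frame(
    participant_id = rep(1:24, times = 2),
    age_group = rep(rep(c("young", "older"), each = 12), 2),
    sex = rep(rep(rep(c("male", "female"), each = 6), 2), 2),
    muscle = rep(c("MG", "LG"), each = 24),
    metric_name = "mean_edge_length",
    value = rnorm(48, 3, 0.5))
  rep_ <- stat_report(cohort_table(d), "mean_edge_length")
  for (m in names(rep_$muscles)) {
    r <- rep_$muscles[[m]]
    expected <- if (all(r$assumptions$shapiro_p > 0.05) &&
                    r$assumptions$levene_p > 0.05) "parametric" else "nonparametric"
    expect_identical(r$branch, expected)
    expect_equal(nrow(r$posthoc), 6)
  }
})
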