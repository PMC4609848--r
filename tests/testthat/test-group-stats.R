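test_that("mean +/- 95% CI summaries follow the t-based closed form", {
  s <- summarize_group(rep(3.2, 10))
  expect_equal(s$mean, 3.2)
  expect_equal(s$ci95_halfwidth, 0)
  s2 <- summarize_group(c(0, 2))
  expect_equal(s2$mean, 1)
  expect_equal(s2$ci95_halfwidth, qt(0.975, 1) * sqrt(2) / sqrt(2),
               tolerance = 1e-12)
  expect_equal(s2$ci95_halfwidth, 12.7062, tolerance = 1e-4)
  ## inversion: an sd chosen to give half-width 0.18 at n = 46 round-trips
  sd_target <- 0.18 * sqrt(46) / qt(0.975, 45)
  x <- scale(rnorm(46)) * sd_target + 1.25
  expect_equal(summarize_group(as.vector(x))$ci95_halfwidth, 0.18,
               tolerance = 1e-10)
  expect_error(summarize_group(5), "at least 2")
})

test_that("independent t-tests agree with a permutation oracle", {
  set.seed(31)
  a <- rnorm(12, 0.3); b <- rnorm(10)
  tt <- ttest_independent(a, b, variant = "student")
  p_perm <- permutation_ttest_p(a, b, n_perm = 20000)
  mc_sd <- sqrt(p_perm * (1 - p_perm) / 20000)
  expect_lt(abs(tt$p - p_perm), 4 * mc_sd + 0.005)
  ## identical groups
  same <- ttest_independent(rep(1, 5), rep(1, 5))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_true(same$degenerate)
})

test_that("summary-statistics bridge recovers printed p-values", {
  ## substantia nigra APT-weighted row, both sample conventions
  for (n in c(46, 23)) {
    r <- ttest_from_summary(1.25, 0.18, n, 0.89, 0.15, n)
    expect_equal(round(r$p, 3), 0.003)
  }
  for (n in c(46, 23)) {
    r <- ttest_from_summary(0.83, 0.13, n, 1.06, 0.12, n)
    expect_equal(round(r$p, 3), 0.010)
  }
  eq <- ttest_from_summary(1, 0.1, 20, 1, 0.1, 20)
  expect_equal(eq$p, 1)
  expect_error(ttest_from_summary(1, 0, 10, 1, 0.1, 10), "positive")
})

test_that("Levene's statistic matches its definitional ANOVA form", {
  skip_if_not_installed("car")
  set.seed(8)
  g <- list(rnorm(12, sd = 1), rnorm(9, sd = 2.5), rnorm(15, sd = 1))
  lv <- levene_test(g)
  ## oracle 1: one-way ANOVA on absolute deviations from group means
  z <- unlist(lapply(g, function(x) abs(x - mean(x))))
  fac <- factor(rep(seq_along(g), lengths(g)))
  aovf <- summary(stats::aov(z ~ fac))[[1]]
  expect_equal(lv$W, aovf$`F value`[1], tolerance = 1e-12)
  expect_equal(lv$p, aovf$`Pr(>F)`[1], tolerance = 1e-12)
  ## oracle 2: car's implementation with mean centering
  cl <- car::leveneTest(unlist(g), fac, center = mean)
  expect_equal(lv$W, cl$`F value`[1], tolerance = 1e-10)
  expect_equal(lv$p, cl$`Pr(>F)`[1], tolerance = 1e-10)
  ## degenerate input
  ident <- levene_test(list(rep(2, 4), rep(2, 5)))
  expect_equal(ident$W, 0)
  expect_equal(ident$p, 1)
})

test_that("Levene's test holds its nominal size on equal-variance groups", {
  set.seed(99)
  rej <- mean(replicate(10000, {
    g <- list(rnorm(25), rnorm(25), rnorm(25))
    levene_test(g)$p < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.01)
})

test_that("one-way ANOVA reduces to t-squared at two groups and matches lm", {
  set.seed(12)
  a <- rnorm(14, 1); b <- rnorm(11, 1.4)
  av <- anova_oneway(list(a, b))
  tt <- ttest_independent(a, b, variant = "student")
  expect_equal(av$F, tt$t^2, tolerance = 1e-10)
  expect_equal(av$p, tt$p, tolerance = 1e-10)
  g3 <- list(rnorm(8), rnorm(12, 0.5), rnorm(10, 1))
  av3 <- anova_oneway(g3)
  lmfit <- anova(lm(y ~ f, data = data.frame(
    y = unlist(g3), f = factor(rep(1:3, lengths(g3))))))
  expect_equal(av3$F, lmfit$`F value`[1], tolerance = 1e-10)
  expect_equal(av3$df_between, 2)
  ident <- anova_oneway(list(rep(1, 3), rep(1, 4), rep(1, 5)))
  expect_equal(ident$F, 0)
  expect_equal(ident$p, 1)
})

test_that("Tukey HSD uses the studentized range and reduces to the pooled t", {
  ## published table value for q(0.95; k = 3, df = 10)
  expect_equal(qtukey(0.95, 3, 10), 3.88, tolerance = 0.01)
  set.seed(4)
  g <- list(a = rnorm(9), b = rnorm(9, 0.8), c = rnorm(9, 1.6))
  th <- tukey_hsd(g)
  expect_equal(nrow(th), 3)
  ## cross-check against stats::TukeyHSD
  df <- data.frame(y = unlist(g), f = factor(rep(names(g), each = 9)))
  ref <- TukeyHSD(aov(y ~ f, data = df))$f
  key <- paste(th$group2, th$group1, sep = "-")
  expect_equal(th$p, unname(ref[key, "p adj"]), tolerance = 1e-8)
  expect_equal(-th$diff, unname(ref[key, "diff"]), tolerance = 1e-12)
  ## k = 2 reduction to the pooled t-test
  g2 <- list(x = rnorm(10), y = rnorm(12, 0.5))
  t2 <- tukey_hsd(g2)
  tt <- ttest_independent(g2$x, g2$y, "student")
  expect_equal(t2$p, tt$p, tolerance = 1e-10)
  ## identical groups
  same <- tukey_hsd(list(rep(1, 4), rep(1, 4)))
  expect_equal(same$p, 1)
})

test_that("Games-Howell matches a long-form hand computation", {
  set.seed(77)
  g <- list(a = rnorm(20, sd = 0.5), b = rnorm(8, 0.5, sd = 2),
            c = rnorm(12, 1, sd = 1.2))
  gh <- games_howell(g)
  hand <- games_howell_hand(g)
  expect_equal(gh$p, hand$p, tolerance = 1e-8)
  expect_true(all(gh$ci_lo <= gh$diff & gh$diff <= gh$ci_hi))
  ## equal-variance, equal-n data: asymptotically close to Tukey
  set.seed(13)
  ge <- list(a = rnorm(25), b = rnorm(25, 0.3), c = rnorm(25, 0.6))
  expect_lt(max(abs(games_howell(ge)$p - tukey_hsd(ge)$p)), 0.02)
  expect_equal(games_howell(list(rep(2, 5), rep(2, 5)))$p, 1)
})

test_that("the analysis chain gates the post hoc family on Levene's test", {
  set.seed(55)
  mk_table <- function(sd_adv) {
    cfg <- cohort_config(n_control = 12, n_early_pd = 10, n_advanced_pd = 10)
    tab <- sample_roi_cohort(cfg, seed = 2)
    tab <- tab[tab$region == "substantia_nigra" & tab$metric == "apt_weighted", ]
    tab$value[tab$stage == "advanced"] <-
      rnorm(sum(tab$stage == "advanced"), 1, sd_adv)
    tab
  }
  res_hom <- analyze_roi_table(mk_table(0.2))
  res_het <- analyze_roi_table(mk_table(5))
  expect_true(all(res_het$three_group$posthoc_method == "games_howell"))
  gate <- res_hom$three_group
  expected <- ifelse(gate$levene_p < 0.05, "games_howell", "tukey")
  expect_equal(gate$posthoc_method, expected)
  expect_true(all(res_hom$posthoc$p >= 0 & res_hom$posthoc$p <= 1))
})

test_that("missing stage labels fall back to the two-group analysis", {
  cfg <- cohort_config(n_control = 6, n_early_pd = 4, n_advanced_pd = 4)
  tab <- sample_roi_cohort(cfg, seed = 3)
  tab$stage[tab$stage == "advanced"] <- "early"
  expect_warning(res <- analyze_roi_table(tab), "incomplete")
  expect_null(res$three_group)
  expect_false(is.null(res$two_group))
})

test_that("subject-level aggregation averages hemispheres first", {
  cfg <- cohort_config(n_control = 6, n_early_pd = 4, n_advanced_pd = 4)
  tab <- sample_roi_cohort(cfg, seed = 9)
  res_h <- analyze_roi_table(tab, sample_unit = "hemisphere")
  res_s <- analyze_roi_table(tab, sample_unit = "subject")
  n_h <- res_h$summaries$n[res_h$summaries$level == "control"][1]
  n_s <- res_s$summaries$n[res_s$summaries$level == "control"][1]
  expect_equal(n_h, 12)
  expect_equal(n_s, 6)
})
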