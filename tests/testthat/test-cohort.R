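test_that("stage effect multipliers derive from the configured targets", {
  cfg <- cohort_config()
  e <- cfg$effects
  expect_true(all(e$amide[e$stage == "control"] == 1))
  expect_true(all(e$fa_lin[e$stage == "control"] == 1))
  sn <- e[e$region == "substantia_nigra", ]
  expect_lt(sn$amide[sn$stage == "advanced"], sn$amide[sn$stage == "early"])
  expect_lt(sn$amide[sn$stage == "early"], 1)
  ca <- e[e$region == "caudate", ]
  expect_gt(ca$amide[ca$stage == "early"], 1)
  expect_gt(ca$amide[ca$stage == "early"], ca$amide[ca$stage == "advanced"])
  expect_error(cohort_config(n_control = 0), "at least one subject")
})

test_that("a null cohort with zero variability is exactly exchangeable", {
  cfg <- cohort_config(n_control = 6, n_early_pd = 4, n_advanced_pd = 4,
                       between_subject_cv = 0, hemisphere_cv = 0,
                       fa_cv = 0, fa_hemisphere_cv = 0, md_cv = 0,
                       md_hemisphere_cv = 0, effects = "null")
  tab <- sample_roi_cohort(cfg, seed = 1)
  spread <- tapply(tab$value, paste(tab$region, tab$metric), function(v)
    diff(range(v)))
  expect_true(all(spread == 0))
  res <- analyze_roi_table(tab)
  expect_true(all(res$two_group$p == 1))
  expect_true(all(res$posthoc$p == 1))
})

test_that("the sampler is seed-deterministic with a stable roster", {
  cfg <- cohort_config(n_control = 5, n_early_pd = 3, n_advanced_pd = 3)
  a <- sample_roi_cohort(cfg, seed = 10)
  b <- sample_roi_cohort(cfg, seed = 10)
  expect_identical(a, b)
  c <- sample_roi_cohort(cfg, seed = 11)
  expect_false(identical(a$value, c$value))
  expect_identical(a[, setdiff(names(a), "value")],
                   c[, setdiff(names(c), "value")])
  expect_equal(length(unique(a$subject_id)), 11)
  expect_equal(sum(a$group == "control"), 5 * 4 * 2 * 4)
})

test_that("sampled group means reproduce the configured stage pattern", {
  cfg <- cohort_config()
  tab <- sample_roi_cohort(cfg, seed = 2)
  m <- function(reg, stg) mean(tab$value[tab$region == reg & tab$stage == stg &
                                           tab$metric == "apt_weighted"])
  expect_gt(m("substantia_nigra", "control"), m("substantia_nigra", "early"))
  expect_gt(m("substantia_nigra", "early"), m("substantia_nigra", "advanced"))
  expect_gt(m("putamen", "early"), m("putamen", "control"))
  expect_gt(m("caudate", "early"), m("caudate", "control"))
  expect_gt(m("caudate", "early"), m("caudate", "advanced"))
  fa <- function(reg, stg) mean(tab$value[tab$region == reg & tab$stage == stg &
                                            tab$metric == "fa"])
  expect_gt(fa("substantia_nigra", "control"), fa("substantia_nigra", "advanced"))
})

test_that("estimated group differences recover the configured effect", {
  cfg <- cohort_config()
  truth <- 1.25 - 0.81 # configured SN APTw control minus advanced
  hits <- vapply(1:40, function(s) {
    tab <- sample_roi_cohort(cfg, seed = 100 + s)
    sn <- tab[tab$region == "substantia_nigra" & tab$metric == "apt_weighted", ]
    a <- sn$value[sn$stage == "control"]; b <- sn$value[sn$stage == "advanced"]
    d <- mean(a) - mean(b)
    se <- sqrt(var(a) / length(a) + var(b) / length(b))
    abs(d - truth) <= 2 * se
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("the imaging cohort is deterministic and labeled consistently", {
  cfg <- cohort_config(n_control = 2, n_early_pd = 2, n_advanced_pd = 2)
  spec <- small_spec(noise_sigma = 0.005)
  co <- generate_cohort(cfg, spec, test_sat(), default_schedule(), seed = 6)
  expect_length(co$subjects, 6)
  expect_equal(vapply(co$subjects, `[[`, character(1), "stage"),
               c("control", "control", "early", "early", "advanced", "advanced"))
  co2 <- generate_cohort(cfg, spec, test_sat(), default_schedule(), seed = 6)
  expect_identical(co$subjects[[1]]$cest$stack, co2$subjects[[1]]$cest$stack)
  expect_identical(co$subjects[[3]]$dwi$dwi, co2$subjects[[3]]$dwi$dwi)
  ## different subjects of the same stage differ through their deviates
  expect_false(identical(co$subjects[[1]]$cest$stack,
                         co$subjects[[2]]$cest$stack))
})
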