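test_that("mixed ANOVA agrees with independent sums-of-squares to 1e-8", {
  for (seed in c(33, 34, 35)) {
    tab <- balanced_integer_cohort(seed)
    a <- mixed_anova(tab, "m", covariate = "none")
    or <- splitplot_oracle(tab)
    eff <- a$effects
    expect_equal(eff$F[eff$effect == "group"], or$F_group, tolerance = 1e-8)
    expect_equal(eff$F[eff$effect == "condition"], or$F_cond, tolerance = 1e-8)
    expect_equal(eff$F[eff$effect == "group:condition"], or$F_int,
                 tolerance = 1e-8)
  }
})

test_that("statistics are invariant to subject relabelling within group", {
  tab <- balanced_integer_cohort()
  a <- mixed_anova(tab, "m", covariate = "none")
  tab2 <- tab
  # swap two subjects of the same group (labels and row order)
  tab2$subject_id[tab2$subject_id == "pd1"] <- "tmp"
  tab2$subject_id[tab2$subject_id == "pd3"] <- "pd1"
  tab2$subject_id[tab2$subject_id == "tmp"] <- "pd3"
  tab2 <- tab2[sample(nrow(tab2)), ]
  b <- mixed_anova(as_cohort_table(tab2), "m", covariate = "none")
  expect_equal(b$effects$F, a$effects$F, tolerance = 1e-10)
  expect_equal(b$epsilon_gg, a$epsilon_gg, tolerance = 1e-10)
})

test_that("identical values in every cell give F = 0 throughout", {
  tab <- balanced_integer_cohort()
  tab$value <- 7
  a <- mixed_anova(tab, "m", covariate = "none")
  expect_equal(a$effects$F, rep(0, 3))
  expect_equal(a$effects$p, rep(1, 3))
})

test_that("Greenhouse-Geisser epsilon and Mauchly match car::Anova", {
  skip_if_not_installed("car")
  set.seed(40)
  tab <- null_cohort(n_per = 10)
  # induce non-sphericity: inflate one condition's variance
  tab$value[tab$condition == "CDT"] <- tab$value[tab$condition == "CDT"] * 3
  a <- mixed_anova(tab, "m", covariate = "none")

  Y <- tapply(tab$value, list(tab$subject_id, tab$condition), mean)
  grp <- factor(tapply(as.character(tab$group), tab$subject_id,
                       `[`, 1L)[rownames(Y)])
  mlm <- lm(Y ~ grp)
  idata <- data.frame(condition = factor(colnames(Y)))
  ca <- summary(car::Anova(mlm, idata = idata, idesign = ~condition),
                multivariate = FALSE)
  expect_equal(a$epsilon_gg,
               unname(ca$pval.adjustments["condition", "GG eps"]),
               tolerance = 1e-6)
  expect_equal(a$mauchly_p,
               unname(ca$sphericity.tests["condition", "p-value"]),
               tolerance = 1e-6)
})

test_that("GG correction increases the p value where the test matters", {
  # shrinking both degrees of freedom lowers the tail probability for small
  # F (the two F distributions cross near F ~ 1); the conservativeness of
  # the correction is a statement about the rejection region, so assert it
  # there
  set.seed(41)
  for (i in 1:5) {
    tab <- null_cohort(n_per = 8)
    tab$value[tab$condition == "ST"] <- tab$value[tab$condition == "ST"] * 2
    a <- mixed_anova(tab, "m", covariate = "none", gg = TRUE)
    eff <- a$effects
    k <- length(a$conditions)
    expect_gt(a$epsilon_gg, 1 / (k - 1))
    expect_lte(a$epsilon_gg, 1)
    w <- eff$effect %in% c("condition", "group:condition") & eff$p <= 0.2
    expect_true(all(eff$p_gg[w] >= eff$p[w] - 1e-12))
  }
})

test_that("subjects with incomplete cells are excluded listwise", {
  set.seed(42)
  tab <- null_cohort(n_per = 5)
  tab <- tab[!(tab$subject_id == "pd1" & tab$condition == "CDT"), ]
  expect_warning(a <- mixed_anova(tab, "m", covariate = "none"), "pd1")
  expect_equal(a$n_subjects, 14L)
  expect_equal(a$excluded, "pd1")
})

test_that("the gait-speed covariate consumes one denominator df", {
  set.seed(43)
  tab <- null_cohort(n_per = 8)
  a0 <- mixed_anova(tab, "m", covariate = "none")
  a1 <- mixed_anova(tab, "m", covariate = "within")
  expect_true("gait_speed" %in% a1$effects$effect)
  expect_false("gait_speed" %in% a0$effects$effect)
  df0 <- a0$effects$df_den[a0$effects$effect == "condition"]
  df1 <- a1$effects$df_den[a1$effects$effect == "condition"]
  expect_equal(df1, df0 - 1)
})

test_that("post hoc t tests are Bonferroni-adjusted over all pairs", {
  set.seed(44)
  # strong condition effect so the omnibus gate opens
  tab <- null_cohort(n_per = 8, groups = c("young", "older"))
  tab$value[tab$condition == "CDT"] <- tab$value[tab$condition == "CDT"] + 3
  ph <- bonferroni_posthoc(tab, "m", "condition")
  expect_equal(nrow(ph), 3L)
  expect_equal(ph$p_adj, pmin(1, 3 * ph$p))
  expect_true(all(ph$p_adj <= 1))

  # two levels: adjusted p equals unadjusted p (m = 1)
  tab2 <- tab[tab$condition != "CDT", ]
  ph2 <- bonferroni_posthoc(as_cohort_table(tab2), "m", "condition",
                            force = TRUE)
  expect_equal(ph2$p_adj, ph2$p)

  # six groups -> 15 pairwise comparisons
  set.seed(45)
  tab6 <- null_cohort(n_per = 4, groups = c("young", "older", "pd",
                                            "stroke", "ms", "lbp"))
  ph6 <- bonferroni_posthoc(tab6, "m", "group", force = TRUE)
  expect_equal(nrow(ph6), 15L)
  expect_equal(ph6$p_adj, pmin(1, 15 * ph6$p))

  # non-significant omnibus effect: gate stays closed
  set.seed(46)
  tabn <- null_cohort(n_per = 8)
  expect_message(phn <- bonferroni_posthoc(tabn, "m", "group"),
                 "not significant")
  expect_equal(nrow(phn), 0L)
})
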