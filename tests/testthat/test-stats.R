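# Statistical workflow: assumption checks, side comparison, RM-ANOVA
# (validated against closed-form sums of squares), Holm post hocs,
# Cohen's d, mixed ANOVA (validated against the gain-score identity),
# paired PRE-POST tests and the fatigue analysis.

sim_table <- function(n = 21, means = c(PRE = 30, ACUTE = 30, POST = 30),
                      sd = 10, rho = 0.8, group = "WG") {
  z <- rnorm(n)
  m <- sapply(names(means), function(s)
    means[[s]] + sd * (sqrt(rho) * z + sqrt(1 - rho) * rnorm(n)))
  colnames(m) <- names(means)
  matrix_to_table(m, group)
}

test_that("Shapiro-Wilk behaves under the null and skips degenerate cells", {
  set.seed(11)
  ps <- replicate(100, {
    tab <- data.frame(task = "t", parameter = "ROM", group = "WG",
                      session = "PRE", participant = 1:50,
                      value = rnorm(50))
    check_assumptions(tab)$p_value[1]
  })
  expect_gte(mean(ps > 0.05), 0.90)
  const <- data.frame(task = "t", parameter = "ROM", group = "WG",
                      session = "PRE", participant = 1:5, value = rep(3, 5))
  out <- check_assumptions(const)
  expect_match(out$note[out$test == "shapiro_wilk"], "skipped")
})

test_that("Levene p-values are near-uniform under equal variances", {
  set.seed(12)
  ps <- replicate(400, {
    tab <- data.frame(task = "t", parameter = "ROM",
                      group = rep(c("WG", "CG"), each = 21),
                      session = "PRE", participant = 1:42,
                      value = rnorm(42, 30, 10))
    out <- check_assumptions(tab)
    out$p_value[out$test == "levene"]
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("side comparison justifies pooling only for symmetric sides", {
  set.seed(13)
  base <- rnorm(21, 100, 10)
  same <- data.frame(participant = rep(1:21, 2),
                     side = rep(c("left", "right"), each = 21),
                     value = c(base, base))
  r <- side_comparison(same)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_true(r$justified)
  # 5-deg systematic asymmetry, n = 21, SD 3: detected almost surely
  hits <- replicate(100, {
    b <- rnorm(21, 100, 10)
    tab <- data.frame(participant = rep(1:21, 2),
                      side = rep(c("left", "right"), each = 21),
                      value = c(b, b + 5 + rnorm(21, 0, 3)))
    side_comparison(tab)$p_value < 0.05
  })
  expect_gte(mean(hits), 0.95)
  one <- data.frame(participant = 1, side = "left", value = 1)
  expect_error(side_comparison(one), "paired")
})

test_that("RM-ANOVA matches closed-form sums of squares and handles ties", {
  set.seed(14)
  tab <- sim_table(means = c(PRE = 29.92, ACUTE = 32.63, POST = 38.73),
                   sd = 16)
  r <- rm_anova_within(tab)
  m <- sapply(c("PRE", "ACUTE", "POST"), function(s)
    tab$value[tab$session == s])
  o <- manual_rm_anova(m)
  expect_equal(r$statistic, o$f, tolerance = 1e-10)
  expect_equal(r$p_value, o$p, tolerance = 1e-10)
  expect_true(r$gg_epsilon > 0.5 && r$gg_epsilon <= 1)
  expect_lte(r$p_value, r$p_gg + 1e-12)
  # identical sessions per participant: F = 0
  flat <- matrix_to_table(matrix(rnorm(21), 21, 3,
                                 dimnames = list(NULL,
                                                 c("PRE", "ACUTE", "POST"))))
  expect_equal(rm_anova_within(flat)$statistic, 0)
  expect_error(rm_anova_within(flat[flat$participant == "WG001", ]),
               "participants")
})

test_that("session effects at published magnitudes are detected", {
  set.seed(15)
  hits <- replicate(120, {
    tab <- sim_table(means = c(PRE = 29.92, ACUTE = 32.63, POST = 38.73),
                     sd = 16)
    rm_anova_within(tab)$p_value < 0.05
  })
  expect_gt(mean(hits), 0.5)
})

test_that("Holm adjustment reproduces the hand-stepped example", {
  # hand-stepped: 0.01*3 = 0.03; max(0.03*2, 0.03) = 0.06; max(0.04, 0.06)
  expect_equal(p.adjust(c(0.01, 0.03, 0.04), "holm"),
               c(0.03, 0.06, 0.06))
  set.seed(16)
  tab <- sim_table(means = c(PRE = 30, ACUTE = 33, POST = 38), sd = 12)
  ph <- holm_posthoc(tab)
  expect_equal(nrow(ph), 3)
  expect_true(all(ph$adjusted_p >= ph$p_value - 1e-12))
  ord <- order(ph$p_value)
  expect_true(all(diff(ph$adjusted_p[ord]) >= -1e-12))
  expect_true(all(ph$adjusted_p <= 1))
  one <- holm_posthoc(tab, pairs = list(c("PRE", "POST")))
  expect_equal(one$adjusted_p, one$p_value)
})

test_that("Cohen's d matches closed forms and band boundaries", {
  expect_equal(cohens_d_summary(29.92, 15.67, 38.73, 17.70)$d,
               (38.73 - 29.92) / sqrt((15.67^2 + 17.70^2) / 2),
               tolerance = 1e-12)
  expect_equal(round(cohens_d_summary(29.92, 15.67, 38.73, 17.70)$d, 3),
               0.527)
  x <- c(1, 2, 3, 4)
  expect_equal(cohens_d(x, x, "paired")$d, 0)
  expect_equal(cohens_d(x, x, "paired")$band, "small")
  expect_error(cohens_d(c(2, 3, 4) + 1, c(2, 3, 4), "paired"),
               "zero variance")
  set.seed(1)
  dv <- rnorm(50)
  dv <- 1 + (dv - mean(dv)) / sd(dv) # mean 1, sd 1 exactly
  expect_equal(cohens_d(dv, rep(0, 50), "paired")$d, 1)
  expect_equal(cohens_d(dv, rep(0, 50), "paired")$band, "very large")
  # left-closed band boundaries
  expect_equal(effect_band(c(0.19, 0.20, 0.49, 0.50, 0.79, 0.80)),
               c("small", "moderate", "moderate", "large", "large",
                 "very large"))
  expect_error(cohens_d(c(1, 1, 1), c(2, 2, 2), "pooled"), "zero variance")
})

test_that("mixed ANOVA interaction equals the gain-score t-test identity", {
  set.seed(17)
  for (i in 1:5) {
    wg <- sim_table(means = c(PRE = 30, POST = 38), sd = 16, group = "WG")
    cg <- sim_table(means = c(PRE = 30, POST = 31), sd = 10, group = "CG")
    tab <- rbind(wg, cg)
    mx <- mixed_rm_anova(tab)
    gw <- wg$value[wg$session == "POST"] - wg$value[wg$session == "PRE"]
    gc <- cg$value[cg$session == "POST"] - cg$value[cg$session == "PRE"]
    o <- manual_interaction(gw, gc)
    expect_equal(mx$interaction$statistic, o$f, tolerance = 1e-8)
    expect_equal(mx$interaction$p_value, o$p, tolerance = 1e-8)
  }
  # identical group trajectories: interaction ~ 0
  set.seed(18)
  m <- matrix(rnorm(42, 30, 5), 21, 2,
              dimnames = list(NULL, c("PRE", "POST")))
  tab0 <- rbind(matrix_to_table(m, "WG"), matrix_to_table(m, "CG"))
  expect_lt(mixed_rm_anova(tab0)$interaction$statistic, 1e-20)
  wg_only <- matrix_to_table(m, "WG")
  expect_error(mixed_rm_anova(wg_only), "groups")
})

test_that("paired PRE-POST test detects a uniform duration shift", {
  set.seed(19)
  hits <- replicate(100, {
    pre <- rnorm(21, 30, 5)
    tab <- matrix_to_table(cbind(PRE = pre,
                                 POST = pre - 3 + rnorm(21, 0, 2)), "CG")
    paired_prepost(tab)$p_value < 0.05
  })
  expect_gte(mean(hits), 0.95)
  flat <- matrix_to_table(cbind(PRE = rep(10, 5), POST = rep(10, 5)), "CG")
  r <- paired_prepost(flat)
  expect_equal(r$p_value, 1)
  expect_equal(r$d, 0)
  expect_error(paired_prepost(flat[c(1, 6), ]), "participants")
})

test_that("fatigue analysis recovers trends, flats and signs", {
  flat <- data.frame(participant = rep(1:10, each = 6),
                     repetition = rep(1:6, 10), value = 30)
  fa <- fatigue_analysis(flat)
  expect_equal(fa$percent_change, 0)
  expect_equal(fa$anova$statistic, 0)
  set.seed(20)
  first <- rnorm(21, 29.66, 10.59)
  up <- do.call(rbind, lapply(1:21, function(i) data.frame(
    participant = i, repetition = 1:6,
    value = first[i] * seq(1, 1.29, length.out = 6) + rnorm(6, 0, 0.5))))
  fu <- fatigue_analysis(up)
  expect_equal(fu$percent_change, 29, tolerance = 0.15)
  expect_lt(fu$first_vs_last$p_value, 0.05)
  down <- transform(up, value = max(up$value) - value + 5)
  expect_lt(fatigue_analysis(down)$percent_change, 0)
  expect_error(fatigue_analysis(flat[flat$repetition == 1, ]),
               "repetitions")
})

test_that("type-I error of both ANOVAs sits near the nominal level", {
  set.seed(21)
  rej_rm <- mean(replicate(400, {
    tab <- sim_table()
    rm_anova_within(tab)$p_value < 0.05
  }))
  rej_mx <- mean(replicate(400, {
    tab <- rbind(sim_table(means = c(PRE = 30, POST = 33), group = "WG"),
                 sim_table(means = c(PRE = 30, POST = 33), group = "CG"))
    mixed_rm_anova(tab)$interaction$p_value < 0.05
  }))
  expect_gt(rej_rm, 0.025); expect_lt(rej_rm, 0.075)
  expect_gt(rej_mx, 0.025); expect_lt(rej_mx, 0.075)
})
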