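test_that("summary statistics match hand computation and a brute oracle", {
  s <- summary_stats(c(2, 4, 6))
  expect_equal(s$n, 3)
  expect_equal(s$mean, 4)
  expect_equal(s$sd, 2)
  expect_equal(s$sem, 2 / sqrt(3), tolerance = 1e-9)
  expect_equal(s$range, 4)
  expect_equal(s$cv_percent, 50)

  sc <- summary_stats(c(5, 5, 5))
  expect_equal(sc$sd, 0)
  expect_equal(sc$cv_percent, 0)

  set.seed(7)
  for (k in 1:20) {
    x <- rnorm(sample(3:30, 1), sample(-5:5, 1), runif(1, 0.1, 3))
    s1 <- summary_stats(x)
    n <- length(x); m <- sum(x) / n
    v <- sum((x - m)^2) / (n - 1)
    expect_equal(s1$mean, m, tolerance = 1e-12)
    expect_equal(s1$sd, sqrt(v), tolerance = 1e-12)
    expect_equal(s1$sem, sqrt(v / n), tolerance = 1e-12)
    expect_equal(s1$range, max(x) - min(x), tolerance = 1e-12)
    # CV is invariant to positive scaling
    expect_equal(summary_stats(3 * x)$cv_percent, s1$cv_percent,
                 tolerance = 1e-9)
  }
  expect_error(summary_stats(c(1)), class = "urokin_argument_error")
  expect_error(summary_stats(c(1, NA)), class = "urokin_argument_error")
})

test_that("coefficient of variation reproduces printed reference rows", {
  expect_equal(coefficient_of_variation(4.88, 1.64), 34L)
  expect_equal(coefficient_of_variation(10.64, 3.69), 35L)
  expect_equal(coefficient_of_variation(-79.55, 18.39), 23L)  # |mean| used
  expect_equal(coefficient_of_variation(7, 0), 0L)
  expect_error(coefficient_of_variation(0, 1),
               class = "urokin_argument_error")
})

test_that("the mixed ANOVA matches a brute-force decomposition", {
  # balanced 2 groups x 3 events x 3 subjects per group, integer data
  set.seed(3)
  d <- tidyr::expand_grid(subject = sprintf("s%d", 1:6),
                          maneuver = c("cough", "valsalva", "pmc"))
  d$group <- ifelse(d$subject %in% sprintf("s%d", 1:3), "control", "sui")
  d$value <- as.numeric(sample(1:20, nrow(d), replace = TRUE))
  fit <- rm_anova_2x3(d)
  oracle <- mixed_anova_oracle(d)
  got <- tidy(fit)
  expect_equal(got$F[match(oracle$effect, got$effect)], oracle$F,
               tolerance = 1e-8)
  expect_equal(glance(fit)$n_subjects, 6)

  # unbalanced groups still run (10 vs 11)
  d2 <- null_metric_table()
  expect_s3_class(rm_anova_2x3(d2), "rm_anova")
})

test_that("degenerate variance structures are handled explicitly", {
  d <- tidyr::expand_grid(subject = sprintf("s%d", 1:6),
                          maneuver = c("cough", "valsalva", "pmc"))
  d$group <- ifelse(d$subject %in% sprintf("s%d", 1:3), "control", "sui")
  d$value <- ifelse(d$group == "control", 1, 3)  # constant within group
  fit <- tidy(rm_anova_2x3(d))
  expect_lt(fit$p[fit$effect == "group"], 1e-10)
  expect_equal(fit$F[fit$effect == "maneuver"], 0)
  expect_equal(fit$p[fit$effect == "maneuver"], 1)
  expect_equal(fit$F[fit$effect == "group:maneuver"], 0)

  # missing cell: explicit error, no silent imputation
  d_miss <- d[-1, ]
  expect_error(rm_anova_2x3(d_miss), class = "urokin_missing_data_error")
})

test_that("ANOVA type-I error is controlled on null cohorts", {
  set.seed(123)
  p <- replicate(1000, {
    d <- null_metric_table()
    tidy(rm_anova_2x3(d))$p[1]
  })
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("pairwise contrasts apply the declared Bonferroni family", {
  set.seed(11)
  d <- null_metric_table()
  res <- pairwise_compare(d)
  expect_equal(nrow(res), 5)
  expect_equal(res$p_bonferroni, pmin(1, 5 * res$p_raw))
  expect_true(all(res$p_bonferroni <= 1))

  # identical samples: t = 0, p = 1
  d0 <- d
  d0$value <- rep(1:21, each = 3) + 0  # same values in both groups per rank
  d0$value[d0$group == "control"] <- 5
  d0$value[d0$group == "sui"] <- 5
  d0$value <- d0$value + as.numeric(factor(d0$subject)) / 100  # within-pair equal
  res0 <- pairwise_compare(d0, default_contrasts()[4, ])  # paired, control
  expect_equal(res0$t, 0, tolerance = 1e-9)
  expect_equal(res0$p_raw, 1, tolerance = 1e-9)

  # n < 2 per arm
  tiny <- d[d$subject %in% c("c01", "s01"), ]
  expect_error(pairwise_compare(tiny, default_contrasts()[1, ]),
               class = "urokin_argument_error")
})

test_that("null cohorts rarely show significant contrasts after correction", {
  set.seed(5)
  hits <- replicate(40, {
    d <- null_metric_table()
    any(pairwise_compare(d)$p_bonferroni < 0.05)
  })
  expect_gte(mean(!hits), 0.9)
})

test_that("cohort summary produces one cell per group-maneuver-roi-metric", {
  set.seed(9)
  d <- null_metric_table()
  s <- cohort_summary(d)
  expect_equal(nrow(s), 6)  # 3 maneuvers x 2 groups, one roi, one metric
  expect_true(all(c("n", "mean", "sd", "sem", "range", "cv_percent")
                  %in% names(s)))
  expect_equal(s$sem, s$sd / sqrt(s$n), tolerance = 1e-12)
})
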