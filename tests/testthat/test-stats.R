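test_that("t-test identities and hand-computed example", {
  same <- unpaired_t_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  # pooled t by hand: means 2 vs 5, pooled sd 1, se = sqrt(2/3)
  tt <- unpaired_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tt$t_statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(tt$t_statistic, -3.674, tolerance = 1e-3)
  expect_equal(tt$degrees_of_freedom, 4)
  expect_equal(tt$p_value, 2 * pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-12)
  expect_equal(tt$p_value, 0.0213, tolerance = 1e-3)
  # sign flips under group swap, p invariant
  rev <- unpaired_t_test(c(4, 5, 6), c(1, 2, 3))
  expect_equal(rev$t_statistic, -tt$t_statistic)
  expect_equal(rev$p_value, tt$p_value)
  expect_error(unpaired_t_test(1, c(1, 2)), "insufficient_n")
})

test_that("summary t-test is sufficient for the raw-data t-test", {
  set.seed(19)
  for (i in 1:12) {
    a <- rnorm(sample(3:10, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:10, 1), mean = runif(1, -1, 1))
    for (ev in c(TRUE, FALSE)) {
      raw <- unpaired_t_test(a, b, ev)
      smry <- t_test_from_summary(mean(a), sd(a), length(a),
                                  mean(b), sd(b), length(b), ev)
      expect_equal(smry$t_statistic, raw$t_statistic, tolerance = 1e-12)
      expect_equal(smry$degrees_of_freedom, raw$degrees_of_freedom,
                   tolerance = 1e-12)
      expect_equal(smry$p_value, raw$p_value, tolerance = 1e-12)
    }
  }
  expect_equal(t_test_from_summary(5, 1, 4, 5, 2, 6)$t_statistic, 0)
})

test_that("published proteinuria contrast is significant under both
           dispersion readings", {
  for (reading in c("sd", "sem")) {
    p <- t_test_from_summary(0.96, 0.31, 7, 2.11, 0.35, 7,
                             dispersion = reading)$p_value
    expect_lt(p, 0.05)
  }
})

test_that("OLS fixture matches the normal equations", {
  fit <- linear_regression(c(1, 2, 3, 4), c(2, 4, 5, 9))
  expect_equal(fit$slope, 2.2, tolerance = 1e-12)
  expect_equal(fit$intercept, -0.5, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1 - 1.8 / 26, tolerance = 1e-12)
  # perfect fit
  perf <- suppressWarnings(linear_regression(1:5, 2 * (1:5) + 1))
  expect_equal(perf$r_squared, 1)
  expect_lt(perf$p_value, 1e-10)
  expect_error(linear_regression(c(1, 1, 1), 1:3), "constant_x")
  expect_error(linear_regression(1:2, 1:2), "insufficient_n")
})

test_that("regression null behaviour and residual orthogonality", {
  set.seed(23)
  x <- rnorm(60); y <- rnorm(60)
  fit <- linear_regression(x, y)
  expect_lt(fit$r_squared, 0.15)
  res <- y - fit$intercept - fit$slope * x
  expect_lt(abs(sum(res * x)) / (sd(x) * sd(y) * 60), 1e-10)
})

test_that("grade-stratified report from raw cases", {
  set.seed(5)
  cases <- data.frame(case_id = sprintf("c%02d", 1:14),
                      density = c(rnorm(7, 226, 30), rnorm(7, 124, 25)))
  meta <- data.frame(case_id = cases$case_id,
                     grade = rep(c("IIa", "III"), each = 7))
  meta$grade_group <- grade_group(meta$grade)
  rep <- grade_stratified_report(cases, meta, variables = "density")
  early <- cases$density[1:7]; late <- cases$density[8:14]
  expect_equal(rep$mean_early, mean(early))
  expect_equal(rep$sd_late, sd(late))
  expect_equal(rep$pooled_mean, mean(c(mean(early), mean(late))))
  expect_equal(rep$p_value, unpaired_t_test(early, late)$p_value)
  # identical groups give p = 1
  cases2 <- cases; cases2$density <- rep(c(1, 2, 3, 4, 5, 6, 7), 2)
  rep2 <- grade_stratified_report(cases2, meta, variables = "density")
  expect_equal(rep2$p_value, 1)
})

test_that("published cohort summaries pool and stratify as printed", {
  rep <- cohort_summary_report(load_cohort_summary())
  prot <- rep[rep$variable == "proteinuria_g_day", ]
  expect_equal(prot$pooled_mean, (0.96 + 2.11) / 2)
  expect_lt(abs(prot$pooled_mean - 1.54), 0.0051)  # printed pooled value
  age <- rep[rep$variable == "age_years", ]
  expect_lt(abs(age$pooled_mean - 60.07), 0.01)
  expect_equal(rep[rep$variable == "n_male", "group_sum"], 11)
  dens <- rep[rep$variable == "podocyte_density_per_1e6um3", ]
  expect_equal(dens$ratio_late_over_early_pct, 100 * 124.5 / 226)
})
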