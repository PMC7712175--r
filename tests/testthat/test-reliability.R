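test_that("consistency ICC matches the two-way ANOVA mean-square oracle", {
  test <- c(1, 2, 3, 4, 5); retest <- c(2, 1, 3, 4, 5)
  # independent oracle: base-R two-way ANOVA decomposition
  d <- data.frame(value = c(test, retest),
                  subject = factor(rep(1:5, 2)),
                  session = factor(rep(1:2, each = 5)))
  ms <- summary(stats::aov(value ~ session + subject, data = d))[[1]]
  msr <- ms["subject", "Mean Sq"]; mse <- ms["Residuals", "Mean Sq"]
  expect_equal(icc_consistency(test, retest, "average"), (msr - mse) / msr)
  expect_equal(icc_consistency(test, retest, "single"), (msr - mse) / (msr + mse))
  # frozen values from the oracle
  expect_equal(icc_consistency(test, retest, "average"), 0.947368421052632)
  expect_equal(icc_consistency(test, retest, "single"), 0.9)

  expect_equal(icc_consistency(c(3, 9, 4, 7), c(3, 9, 4, 7)), 1)
})

test_that("ICC is invariant to shift and positive rescale, undefined without spread", {
  withr::with_seed(2, {
    test <- rnorm(30, 10, 3); retest <- test + rnorm(30)
  })
  base <- icc_consistency(test, retest)
  expect_equal(icc_consistency(test + 100, retest + 100), base)
  expect_equal(icc_consistency(test * 7, retest * 7), base)
  expect_error(icc_consistency(rep(1, 5), rep(1, 5)),
               class = "balancemdc_degenerate")
  expect_error(icc_consistency(1:3, 1:2), class = "balancemdc_invalid_spec")
  expect_error(icc_consistency(1, 1), class = "balancemdc_insufficient_data")
})

test_that("pooled SD is the RMS of the session SDs", {
  expect_equal(pooled_sd(0.3, 0.3), 0.3)
  expect_equal(pooled_sd(1.9, 1.8), sqrt((1.9^2 + 1.8^2) / 2))
  expect_equal(pooled_sd(1.9, 1.8), 1.85067555, tolerance = 1e-7)
  for (x in c(0, 0.5, 2, 11)) expect_equal(pooled_sd(x, x), x)
  expect_error(pooled_sd(-1, 1), class = "balancemdc_invalid_argument")
})

test_that("SEM and MDC95 follow their defining formulas", {
  expect_equal(sem(5, 1), 0)
  expect_equal(sem(0.3, 0.96), 0.06)
  expect_equal(sem(2.4, 0), 2.4)
  expect_error(sem(1, 1.2), class = "balancemdc_invalid_argument")

  expect_equal(mdc95(0), 0)
  expect_equal(mdc95(1), 1.96 * sqrt(2))
  expect_equal(mdc95(1), 2.77185858, tolerance = 1e-7)
  expect_error(mdc95(-0.1), class = "balancemdc_invalid_argument")

  # printed-table round trip: SDs 1.9/1.8 with ICC 0.85 give MDC95 2.0 (1 d.p.)
  m <- mdc95(sem(pooled_sd(1.9, 1.8), 0.85))
  expect_equal(round_half_up(m, 1), 2.0)
  expect_equal(round_half_up(mdc_effect_size(m, 1.9), 1), 1.0)

  expect_equal(mdc_effect_size(0, 2), 0)
  expect_equal(mdc_effect_size(3.7, 3.7), 1)
  expect_error(mdc_effect_size(1, 0), class = "balancemdc_invalid_argument")
})

test_that("SEM never exceeds the pooled SD and MDC shrinks as ICC grows", {
  iccs <- seq(-0.5, 1, by = 0.1)
  sems <- sem(2, iccs)
  expect_true(all(sems[iccs >= 0] <= 2 + 1e-12))
  expect_equal(sem(2, 0), 2)
  expect_true(all(diff(mdc95(sems)) < 0))
  expect_true(all(mdc95(sems[-length(sems)]) > 0) && mdc95(sems[length(sems)]) == 0)
})

test_that("ICC qualitative bands split at 0.40, 0.60 and 0.75", {
  got <- classify_icc(c(-0.2, 0.39, 0.40, 0.59, 0.60, 0.74, 0.75, 1.00))
  expect_equal(as.character(got),
               c("poor", "poor", "fair", "fair", "good", "good",
                 "excellent", "excellent"))
  expect_error(classify_icc(NaN), class = "balancemdc_invalid_argument")
})

test_that("sample size follows the normal-variate precision formula", {
  z2 <- qnorm(0.975)^2
  expect_equal(sample_size(sd = 3, d = 3), z2)
  expect_equal(sample_size(sd = 3, d = 1.5), 4 * sample_size(sd = 3, d = 3))
  expect_equal(sample_size(sd = 2, d = 1, alpha = 0.10),
               qnorm(0.95)^2 * 4)
  expect_error(sample_size(0, 1), class = "balancemdc_invalid_argument")
  expect_error(sample_size(1, 1, alpha = 1), class = "balancemdc_invalid_argument")
})

test_that("reliability_table reproduces degenerate and generative cohorts", {
  # retest identical to test: perfect reliability, zero MDC
  coh <- simple_cohort(c(4, 6, 8, 10), c(4, 6, 8, 10))
  rel <- reliability_table(coh)
  expect_s3_class(rel, "balance_reliability")
  expect_equal(rel$icc, 1)
  expect_equal(rel$mdc95, 0)
  expect_equal(as.character(rel$icc_label), "excellent")

  # two variables keep their names and first-appearance order
  coh2 <- dplyr::bind_rows(
    simple_cohort(c(1, 2, 3), c(1.1, 2.2, 2.9), variable = "Zeta"),
    simple_cohort(c(5, 7, 9), c(5, 8, 9), variable = "Alpha"))
  rel2 <- reliability_table(coh2)
  expect_equal(rel2$variable, c("Zeta", "Alpha"))

  # generative oracle: MDC column estimates 1.96 sqrt(2) sem_within
  vars <- tibble::tibble(variable = "speed", mean = 10, sd_between = 4, sem_within = 1.5)
  coh3 <- gen_testretest_cohort(cohort_spec(vars, n_subjects = 200, seed = 14))
  rel3 <- reliability_table(coh3)
  expect_lt(abs(rel3$mdc95 - 1.96 * sqrt(2) * 1.5) / (1.96 * sqrt(2) * 1.5), 0.15)

  # unbalanced data is refused with the offenders named
  bad <- coh[-1, ]
  err <- expect_error(reliability_table(bad), class = "balancemdc_missing_pair")
  expect_match(conditionMessage(err), "S01")
})

test_that("the star flag marks high-ICC variables and the report layout is stable", {
  vars <- tibble::tibble(
    task = c("RSEO", "RSEO"), variable = c("good_var", "noisy_var"),
    mean = c(10, 10), sd_between = c(4, 1), sem_within = c(0.5, 2))
  coh <- gen_testretest_cohort(cohort_spec(vars, n_subjects = 80, seed = 6))
  rel <- reliability_table(coh)
  expect_true(rel$star[rel$variable == "good_var"])   # true ICC ~ 0.98
  expect_false(rel$star[rel$variable == "noisy_var"]) # true ICC = 0.2

  fmt <- format_reliability(rel)
  expect_equal(names(fmt),
               c("Balance Tasks", "Variables", "Test µ (SD)", "Retest µ (SD)",
                 "ICC", "MDC95_es", "MDC95"))
  expect_match(fmt$Variables[fmt$`Balance Tasks` == "RSEO"][1], "\\*")
})
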