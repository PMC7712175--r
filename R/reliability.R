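#' Test-retest intraclass correlation (two-way, consistency)
#'
#' Computes the consistency ICC from the subjects x sessions two-way ANOVA
#' mean squares, for the two-session (k = 2) test-retest design. With
#' `MSR` the between-subjects mean square and `MSE` the residual mean square
#' after removing the session effect (no subject x session interaction is
#' estimable at k = 2):
#'
#' * `measures = "single"` (default): `(MSR - MSE) / (MSR + (k-1) MSE)` —
#'   the reliability of one measurement, often labelled ICC(3,1)/ICC(C,1).
#' * `measures = "average"`: `(MSR - MSE) / MSR` — the Spearman-Brown
#'   reliability of the average of the k sessions, labelled ICC(3,k).
#'
#' The single-measures form is the default because the downstream chain
#' `SEM = SD_pooled * sqrt(1 - ICC)` recovers the within-subject standard
#' error of measurement only under it (see the methods vignette).
#'
#' @param test,retest numeric vectors of paired session values (same subject
#'   order, length >= 2).
#' @param measures `"single"` or `"average"`.
#' @return the ICC (unitless, <= 1).
#' @examples
#' icc_consistency(c(1, 2, 3, 4, 5), c(2, 1, 3, 4, 5)) # 0.9
#' icc_consistency(c(1, 2, 3, 4, 5), c(2, 1, 3, 4, 5), measures = "average")
#' @export
icc_consistency <- function(test, retest, measures = c("single", "average")) {
  measures <- match.arg(measures)
  if (length(test) != length(retest)) {
    stop_invalid_spec("`test` and `retest` must pair up one value per subject.")
  }
  n <- length(test)
  if (n < 2) stop_insufficient("ICC needs at least 2 subjects.")
  if (anyNA(test) || anyNA(retest)) {
    stop_invalid_spec("missing values: every subject needs both sessions.")
  }
  k <- 2
  x <- cbind(test, retest)
  grand <- mean(x)
  subj_means <- rowMeans(x)
  sess_means <- colMeans(x)
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_sess <- n * sum((sess_means - grand)^2)
  ss_tot <- sum((x - grand)^2)
  msr <- ss_subj / (n - 1)
  mse <- (ss_tot - ss_subj - ss_sess) / ((n - 1) * (k - 1))
  if (msr <= 0) {
    stop_degenerate("zero between-subject variance: ICC undefined.")
  }
  if (measures == "average") (msr - mse) / msr
  else (msr - mse) / (msr + (k - 1) * mse)
}

#' Pooled standard deviation of the two sessions
#'
#' Root mean square of the test and retest SDs (equal group sizes):
#' `sqrt((sd_test^2 + sd_retest^2) / 2)`.
#'
#' @param sd_test,sd_retest session standard deviations (>= 0).
#' @return pooled SD in the variable's units.
#' @examples
#' pooled_sd(1.9, 1.8)
#' @export
pooled_sd <- function(sd_test, sd_retest) {
  if (any(sd_test < 0) || any(sd_retest < 0)) {
    stop_invalid("standard deviations must be >= 0.")
  }
  sqrt((sd_test^2 + sd_retest^2) / 2)
}

#' Standard error of measurement
#'
#' `SEM = SD_pooled * sqrt(1 - ICC)`: the within-subject measurement noise
#' implied by the between-subject spread and the test-retest reliability.
#'
#' @param sd_pooled pooled session SD (see [pooled_sd()]).
#' @param icc intraclass correlation, at most 1.
#' @return SEM in the variable's units.
#' @examples
#' sem(0.3, 0.96)
#' @export
sem <- function(sd_pooled, icc) {
  if (any(icc > 1)) stop_invalid("`icc` cannot exceed 1.")
  if (any(sd_pooled < 0)) stop_invalid("`sd_pooled` must be >= 0.")
  sd_pooled * sqrt(1 - icc)
}

#' Minimal detectable change at 95% confidence
#'
#' `MDC95 = 1.96 * sqrt(2) * SEM`: the smallest test-retest difference that
#' exceeds measurement variability with 95% confidence. Changes below it are
#' indistinguishable from test noise.
#'
#' @param sem standard error of measurement (>= 0).
#' @return MDC95 in the variable's units.
#' @examples
#' mdc95(1) # 2.7719
#' @export
mdc95 <- function(sem) {
  if (any(sem < 0)) stop_invalid("`sem` must be >= 0.")
  1.96 * sqrt(2) * sem
}

#' MDC effect size
#'
#' `MDC95 / SD_test`: the minimal detectable change expressed in units of
#' the baseline between-subject SD — the number of standard deviations the
#' experiment can detect.
#'
#' @param mdc95 minimal detectable change.
#' @param sd_test standard deviation of the first (test) session, > 0.
#' @return unitless ratio.
#' @export
mdc_effect_size <- function(mdc95, sd_test) {
  if (any(sd_test <= 0)) stop_invalid("`sd_test` must be > 0.")
  mdc95 / sd_test
}

#' Qualitative ICC band
#'
#' Classifies an ICC on the conventional agreement scale: below 0.40 poor;
#' 0.40-0.59 fair; 0.60-0.74 good; 0.75-1.00 excellent.
#'
#' @param icc numeric vector of finite ICCs.
#' @return factor with levels poor < fair < good < excellent.
#' @examples
#' classify_icc(c(0.39, 0.40, 0.60, 0.75))
#' @export
classify_icc <- function(icc) {
  if (any(!is.finite(icc))) stop_invalid("`icc` must be finite.")
  cut(icc, breaks = c(-Inf, 0.40, 0.60, 0.75, Inf), right = FALSE,
      labels = c("poor", "fair", "good", "excellent"))
}

#' Sample size for estimating a mean to a given precision
#'
#' `N = z^2 * SD^2 / d^2` with `z` the standard normal quantile at
#' `1 - alpha/2`, `SD` the expected variable SD and `d` the absolute
#' precision the study requires. Returned unrounded.
#'
#' @param sd expected standard deviation of the variable (> 0).
#' @param d absolute error/precision (> 0), same units as `sd`.
#' @param alpha two-sided type-I error rate (default 0.05, z = 1.96).
#' @return required sample size (real, unrounded).
#' @examples
#' sample_size(sd = 6, d = 4.1) # about 8.2
#' @export
sample_size <- function(sd, d, alpha = 0.05) {
  if (sd <= 0 || d <= 0 || alpha <= 0 || alpha >= 1) {
    stop_invalid("need sd > 0, d > 0 and 0 < alpha < 1.")
  }
  (qnorm(1 - alpha / 2) * sd / d)^2
}

#' Test-retest reliability and MDC table
#'
#' Computes, per variable, the session means and SDs, the consistency ICC,
#' SEM, MDC95 and MDC effect size, the qualitative ICC band, and a star flag
#' marking the most reliable variables (ICC at or above `star_icc` within
#' their task block).
#'
#' @param cohort long-format cohort: columns `subject`, `session`
#'   (`"test"`/`"retest"`), `variable`, `value`, and optionally `task`.
#' @param measures ICC form passed to [icc_consistency()] (default
#'   `"single"`).
#' @param star_icc ICC threshold for the low-MDC star flag (default 0.83).
#' @return a `balance_reliability` tibble with one row per (task,) variable:
#'   `mean_test`, `sd_test`, `mean_retest`, `sd_retest`, `icc`, `icc_label`,
#'   `sem`, `mdc95`, `mdc95_es`, `star`. Attribute `n_subjects` records the
#'   cohort size.
#' @examples
#' spec <- cohort_spec(
#'   tibble::tibble(variable = "RMS", mean = 6, sd_between = 3, sem_within = 1),
#'   n_subjects = 50, seed = 7
#' )
#' reliability_table(gen_testretest_cohort(spec))
#' @export
reliability_table <- function(cohort, measures = c("single", "average"),
                              star_icc = 0.83) {
  measures <- match.arg(measures)
  cohort <- as_tibble(cohort)
  needed <- c("subject", "session", "variable", "value")
  if (!all(needed %in% names(cohort))) {
    stop_invalid_spec(paste0(
      "`cohort` must have columns ", paste(needed, collapse = ", "), "."))
  }
  if (!all(cohort$session %in% c("test", "retest"))) {
    stop_invalid_spec('`session` must be "test" or "retest".')
  }
  keys <- intersect(c("task", "variable"), names(cohort))

  counts <- cohort |>
    dplyr::count(dplyr::across(dplyr::all_of(c(keys, "subject", "session"))))
  bad <- counts |>
    tidyr::pivot_wider(names_from = "session", values_from = "n",
                       values_fill = 0L) |>
    dplyr::filter(.data$test != 1L | .data$retest != 1L)
  if (nrow(bad) > 0) {
    offenders <- utils::head(
      paste(bad$subject, bad$variable, sep = " / "), 5)
    abort_invalid(
      paste0("unbalanced cohort: every subject needs exactly one test and ",
             "one retest per variable. Offenders: ",
             paste(offenders, collapse = "; "),
             if (nrow(bad) > 5) " ..." else ""),
      class = "balancemdc_missing_pair")
  }

  wide <- cohort |>
    tidyr::pivot_wider(names_from = "session", values_from = "value")
  # preserve first-appearance variable order (report order)
  wide <- wide[order(match(
    do.call(paste, wide[keys]),
    unique(do.call(paste, cohort[keys])))), ]

  out <- wide |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_test = mean(.data$test), sd_test = sd(.data$test),
      mean_retest = mean(.data$retest), sd_retest = sd(.data$retest),
      icc = icc_consistency(.data$test, .data$retest, measures = measures),
      .groups = "drop"
    )
  out <- out[order(match(
    do.call(paste, out[keys]),
    unique(do.call(paste, cohort[keys])))), ]
  out <- out |>
    dplyr::mutate(
      icc_label = classify_icc(.data$icc),
      sem = sem(pooled_sd(.data$sd_test, .data$sd_retest), .data$icc),
      mdc95 = mdc95(.data$sem),
      mdc95_es = mdc_effect_size(.data$mdc95, .data$sd_test),
      star = .data$icc >= star_icc
    )
  n_subjects <- length(unique(cohort$subject))
  structure(out, class = c("balance_reliability", class(out)),
            n_subjects = n_subjects, measures = measures,
            star_icc = star_icc)
}

#' Format a reliability table for reporting
#'
#' Produces the conventional report layout: one row per variable with
#' columns `Test µ (SD)`, `Retest µ (SD)`, `ICC`, `MDC95_es`, `MDC95`.
#' Means, SDs and MDC values are rounded (half-up) to one decimal, ICC to
#' two decimals; starred variables get an asterisk after their name.
#'
#' @param rel a [reliability_table()] result.
#' @return tibble in display form.
#' @export
format_reliability <- function(rel) {
  fmt1 <- function(x) formatC(round_half_up(x, 1), format = "f", digits = 1)
  lab <- paste0(rel$variable, ifelse(rel$star, " *", ""))
  out <- tibble(
    Variables = lab,
    `Test µ (SD)` = sprintf("%s (%s)", fmt1(rel$mean_test), fmt1(rel$sd_test)),
    `Retest µ (SD)` = sprintf("%s (%s)", fmt1(rel$mean_retest), fmt1(rel$sd_retest)),
    ICC = formatC(round_half_up(rel$icc, 2), format = "f", digits = 2),
    MDC95_es = fmt1(rel$mdc95_es),
    MDC95 = fmt1(rel$mdc95)
  )
  if ("task" %in% names(rel)) {
    out <- dplyr::bind_cols(tibble(`Balance Tasks` = rel$task), out)
  }
  out
}

#' @rdname format_reliability
#' @param path file path for the delimited report.
#' @export
write_reliability_report <- function(rel, path) {
  readr::write_csv(format_reliability(rel), path)
  invisible(path)
}
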