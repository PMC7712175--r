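#' Cohort generator parameters matching the reference reliability panel
#'
#' Converts the printed reference panel ([reference_reliability()]) into
#' generative parameters for [cohort_spec()]: `mean` is the test-session
#' mean, `sem_within` follows from the printed pooled SD and ICC
#' (`SEM = SD_pooled * sqrt(1 - ICC)`), and `sd_between` is the remaining
#' between-subject spread `sqrt(max(SD_pooled^2 - SEM^2, 0))`.
#'
#' @param reference a reference panel tibble (default
#'   [reference_reliability()]).
#' @return tibble with columns `task`, `variable`, `mean`, `sd_between`,
#'   `sem_within`.
#' @export
reference_cohort_variables <- function(reference = reference_reliability()) {
  pooled <- pooled_sd(reference$sd_test, reference$sd_retest)
  s <- sem(pooled, reference$icc)
  tibble(
    task = reference$task,
    variable = reference$variable,
    mean = reference$mean_test,
    sd_between = sqrt(pmax(pooled^2 - s^2, 0)),
    sem_within = s
  )
}

#' Simulate a full synthetic study to disk
#'
#' Writes, under `out_dir`: one quiet-stance COP trajectory per static task
#' (`sway_<task>.csv`), one LOS trial (`los.csv`), a test-retest cohort for
#' the full variable panel (`cohort.csv`), MDC thresholds
#' (`thresholds.csv`), and a simulated patient's pre/post panels
#' (`patient_pre.csv`, `patient_post.csv`; the patient improves: static
#' variables shift down and LOS variables up by 1.5 MDC around the
#' reference means). All randomness derives from `seed`; identical calls
#' produce byte-identical files.
#'
#' @param out_dir output directory, created if missing.
#' @param seed integer seed.
#' @param n_subjects cohort size (default 34).
#' @param reference reliability panel supplying the generative parameters.
#' @return named list of the file paths written, invisibly.
#' @export
pipeline_simulate <- function(out_dir, seed = 1, n_subjects = 34,
                              reference = reference_reliability()) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (!is.numeric(seed) || seed != round(seed)) {
    stop_config("`seed` must be an integer.")
  }
  seed <- as.integer(seed)
  message(sprintf("[balancemdc %s] simulate: seed=%d, n_subjects=%d, out=%s",
                  as.character(utils::packageVersion("balancemdc")),
                  seed, n_subjects, out_dir))
  paths <- list()
  tasks <- c("RSEO", "RSEC", "SSEO", "SSEC")
  for (i in seq_along(tasks)) {
    traj <- gen_sway_trajectory(sway_spec(tasks[i], seed = seed + i))
    paths[[paste0("sway_", tasks[i])]] <- write_cop_trajectory(
      traj, file.path(out_dir, paste0("sway_", tolower(tasks[i]), ".csv")))
  }
  los <- gen_los_trajectory(los_spec(control_noise_mm = 2, seed = seed + 5))
  paths$los <- write_cop_trajectory(los, file.path(out_dir, "los.csv"))

  vars <- reference_cohort_variables(reference)
  cohort <- gen_testretest_cohort(
    cohort_spec(vars, n_subjects = n_subjects, seed = seed + 6))
  paths$cohort <- write_cohort(cohort, file.path(out_dir, "cohort.csv"))

  thr <- reference[c("task", "variable", "mdc95")]
  paths$thresholds <- readr::write_csv(thr, file.path(out_dir, "thresholds.csv"))
  paths$thresholds <- file.path(out_dir, "thresholds.csv")

  # improving patient: static down, dynamic up, by 1.5 MDC
  shift <- ifelse(vars$task == "LOS", 1.5, -1.5) * reference$mdc95
  pairs <- purrr::map2(vars$mean, seq_len(nrow(vars)), function(m, i) {
    gen_patient_pair(patient_pair_spec(m, shift[i], vars$sem_within[i],
                                       seed = seed + 100 + i))
  })
  pre <- post <- reference[c("task", "variable", "units")]
  pre$value <- purrr::map_dbl(pairs, "pre")
  post$value <- purrr::map_dbl(pairs, "post")
  paths$patient_pre <- write_balance_variables(
    pre, file.path(out_dir, "patient_pre.csv"))
  paths$patient_post <- write_balance_variables(
    post, file.path(out_dir, "patient_post.csv"))
  invisible(paths)
}

#' Reliability analysis from a cohort file
#'
#' Reads a long-format cohort, computes the reliability/MDC table and writes
#' the report-shaped output (columns `Test µ (SD)`, `Retest µ (SD)`, `ICC`,
#' `MDC95_es`, `MDC95`).
#'
#' @param cohort_file cohort CSV (`subject,session,variable,value`).
#' @param out_file report CSV to write (optional).
#' @param ... passed to [reliability_table()].
#' @return the `balance_reliability` tibble, invisibly when writing.
#' @export
pipeline_reliability <- function(cohort_file, out_file = NULL, ...) {
  rel <- reliability_table(read_cohort(cohort_file), ...)
  if (!is.null(out_file)) {
    write_reliability_report(rel, out_file)
    return(invisible(rel))
  }
  rel
}

#' Patient monitoring from pre/post files
#'
#' Reads the pre- and post-treatment panels and the MDC thresholds, runs
#' [monitor_patient()], writes the report table and (optionally) the
#' change-versus-MDC plot.
#'
#' @param pre_file,post_file balance-variable CSVs.
#' @param thresholds_file MDC threshold CSV (`variable,mdc95`).
#' @param out_file report CSV to write (optional).
#' @param plot_file image file for [plot_change()] (optional; any device
#'   [ggplot2::ggsave()] supports).
#' @return the `balance_mbd` tibble, invisibly when writing.
#' @export
pipeline_monitor <- function(pre_file, post_file, thresholds_file,
                             out_file = NULL, plot_file = NULL) {
  res <- monitor_patient(
    read_balance_variables(pre_file),
    read_balance_variables(post_file),
    read_mdc_thresholds(thresholds_file)
  )
  if (!is.null(out_file)) write_monitor_report(res, out_file)
  if (!is.null(plot_file)) {
    ggplot2::ggsave(plot_file, plot_change(res), width = 7,
                    height = 0.28 * nrow(res) + 1.5, limitsize = FALSE)
  }
  if (is.null(out_file) && is.null(plot_file)) res else invisible(res)
}

#' Extract balance variables from a trajectory file
#'
#' Reads a COP trajectory (or four-load-cell force file plus geometry),
#' extracts the task's variable panel and optionally writes it.
#'
#' @param traj_file trajectory CSV (`time_s,ml_mm,ap_mm[,target_dir]`).
#' @param task task label; `"LOS"` requires the `target_dir` column.
#' @param out_file panel CSV to write (optional).
#' @param geom octagon geometry for LOS (default [los_geometry()]).
#' @return the variable panel tibble, invisibly when writing.
#' @export
pipeline_metrics <- function(traj_file, task, out_file = NULL,
                             geom = los_geometry()) {
  traj <- read_cop_trajectory(traj_file)
  vars <- extract_variables(traj, task, geom = if (task == "LOS") geom)
  if (!is.null(out_file)) {
    write_balance_variables(vars, out_file)
    return(invisible(vars))
  }
  vars
}
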