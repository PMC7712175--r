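balancemdc_extdata <- function(file) {
  system.file("extdata", file, package = "balancemdc", mustWork = TRUE)
}

#' Bundled reference test-retest reliability panel
#'
#' Reliability reference for the full balance battery, from a test-retest
#' study of 34 healthy young adults on a portable four-load-cell platform
#' (two sessions six hours apart): per-variable session means and SDs, the
#' reported ICC, the MDC95 and its effect size, and the star flag marking
#' the most reliable variables of each task block. Values are as printed in
#' the original report (one decimal; ICC two decimals), so recomputing MDC95
#' from the rounded SDs and ICC reproduces the tabled MDC95 only up to
#' input-rounding error; the MDC95 column itself is the threshold set used
#' for patient monitoring.
#'
#' @return tibble with columns `task`, `variable`, `units`, `mean_test`,
#'   `sd_test`, `mean_retest`, `sd_retest`, `icc`, `mdc95_es`, `mdc95`,
#'   `star`.
#' @seealso [patient01_example()], [reliability_table()]
#' @examples
#' reference_reliability()
#' @export
reference_reliability <- function() {
  readr::read_csv(balancemdc_extdata("testretest_reference.csv"),
                  show_col_types = FALSE)
}

#' Bundled worked example: one vertigo patient, pre and post treatment
#'
#' Balance-variable panels measured for one patient with a vestibular
#' balance disorder before and three months after vestibular rehabilitation,
#' with the MDC95 thresholds from the healthy reference cohort
#' ([reference_reliability()]). Running [monitor_patient()] on these panels
#' reproduces the clinical monitoring report this package is built around.
#' Two LOS limit rows of the source record (Forward-rightward, Rightward)
#' contain implausible pre values as printed and are kept verbatim.
#'
#' @return list of three tibbles: `pre` and `post` (columns `task`,
#'   `variable`, `units`, `value`) and `thresholds` (columns `task`,
#'   `variable`, `mdc95`).
#' @examples
#' p01 <- patient01_example()
#' monitor_patient(p01$pre, p01$post, p01$thresholds)
#' @export
patient01_example <- function() {
  list(
    pre = read_balance_variables(balancemdc_extdata("patient01_pre.csv")),
    post = read_balance_variables(balancemdc_extdata("patient01_post.csv")),
    thresholds = read_mdc_thresholds(balancemdc_extdata("mdc_thresholds.csv"))
  )
}

#' Read and write balance-variable panels and MDC thresholds
#'
#' Balance-variable panels are CSV with columns `task`, `variable`, `units`,
#' `value`; threshold tables have columns `variable`, `mdc95` (optionally
#' `task`).
#'
#' @param path file path.
#' @return a tibble.
#' @name panel_io
#' @export
read_balance_variables <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("variable", "value") %in% names(x))) {
    stop_invalid_spec("balance-variable files need columns variable, value.")
  }
  x
}

#' @rdname panel_io
#' @param vars a balance-variable tibble (e.g. from [extract_variables()]).
#' @export
write_balance_variables <- function(vars, path) {
  readr::write_csv(vars, path)
  invisible(path)
}

#' @rdname panel_io
#' @export
read_mdc_thresholds <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("variable", "mdc95") %in% names(x))) {
    stop_config("threshold files need columns variable, mdc95.")
  }
  if (any(x$mdc95 <= 0)) stop_config("all MDC thresholds must be > 0.")
  x
}

#' @rdname panel_io
#' @export
read_cohort <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("subject", "session", "variable", "value") %in% names(x))) {
    stop_invalid_spec("cohort files need columns subject, session, variable, value.")
  }
  x
}

#' @rdname panel_io
#' @param cohort a long-format cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}
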