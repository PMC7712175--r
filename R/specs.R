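#' Specification of a synthetic quiet-stance sway recording
#'
#' Parameters of the stochastic sway generator used by
#' [gen_sway_trajectory()]. Each axis (mediolateral ML, anteroposterior AP)
#' follows a stationary mean-reverting Ornstein-Uhlenbeck process around the
#' platform centre, so the long-run standard deviation of each coordinate is
#' exactly `sigma_*_mm` and the autocorrelation decays with time constant
#' `tau_s`. Default sway amplitudes depend on the task and are ordered
#' RSEO < RSEC < SSEO < SSEC: removing vision and standing on foam both
#' increase sway, which is the contrast the Romberg/CTSIB-M battery is
#' designed to expose.
#'
#' @param task one of `"RSEO"`, `"RSEC"`, `"SSEO"`, `"SSEC"` (rigid/soft
#'   surface crossed with eyes open/closed).
#' @param duration_s trial duration in seconds (default 30 s).
#' @param fs_hz sampling rate in Hz (default 40 Hz).
#' @param sigma_ml_mm,sigma_ap_mm stationary sway SD per axis in mm; defaults
#'   depend on `task` (see Details).
#' @param tau_s mean-reversion time constant in seconds.
#' @param seed optional integer seed; generation is bit-reproducible under a
#'   fixed seed.
#'
#' @details Default per-task sigmas (ML, AP in mm): RSEO (2.5, 3.0),
#'   RSEC (3.5, 4.0), SSEO (4.0, 4.5), SSEC (7.5, 9.0). These place the
#'   resulting RMS and displacement ranges near values typical of healthy
#'   young adults on a force platform.
#'
#' @return an object of class `sway_spec`.
#' @seealso [gen_sway_trajectory()]
#' @export
sway_spec <- function(task = c("RSEO", "RSEC", "SSEO", "SSEC"),
                      duration_s = 30, fs_hz = 40,
                      sigma_ml_mm = NULL, sigma_ap_mm = NULL,
                      tau_s = 1, seed = NULL) {
  task <- match.arg(task)
  defaults <- list(
    RSEO = c(ml = 2.5, ap = 3.0),
    RSEC = c(ml = 3.5, ap = 4.0),
    SSEO = c(ml = 4.0, ap = 4.5),
    SSEC = c(ml = 7.5, ap = 9.0)
  )[[task]]
  if (is.null(sigma_ml_mm)) sigma_ml_mm <- defaults[["ml"]]
  if (is.null(sigma_ap_mm)) sigma_ap_mm <- defaults[["ap"]]
  if (!is.numeric(duration_s) || duration_s <= 0) {
    stop_invalid_spec("`duration_s` must be a positive number of seconds.")
  }
  if (!is.numeric(fs_hz) || fs_hz <= 0) {
    stop_invalid_spec("`fs_hz` must be a positive sampling rate in Hz.")
  }
  if (sigma_ml_mm < 0 || sigma_ap_mm < 0) {
    stop_invalid_spec("sway SDs `sigma_ml_mm`/`sigma_ap_mm` must be >= 0.")
  }
  if (tau_s <= 0) stop_invalid_spec("`tau_s` must be > 0.")
  structure(
    list(task = task, duration_s = duration_s, fs_hz = fs_hz,
         sigma_ml_mm = sigma_ml_mm, sigma_ap_mm = sigma_ap_mm,
         tau_s = tau_s, seed = seed),
    class = "sway_spec"
  )
}

#' Specification of a synthetic limits-of-stability (LOS) trial
#'
#' Parameters for [gen_los_trajectory()]. The simulated subject leans towards
#' each of the eight octagon directions in turn (clockwise from Forward),
#' tracing an out-and-back excursion whose peak is
#' `radius_target_mm * (1 + overshoot_frac)` plus Gaussian tracking noise.
#'
#' @param radius_target_mm target excursion per direction in mm; a single
#'   value is recycled to all 8 directions (default 80 mm).
#' @param dwell_s seconds spent on each direction.
#' @param control_noise_mm SD of the Gaussian tracking noise added to both
#'   coordinates (0 = perfectly controlled excursion).
#' @param overshoot_frac fractional overshoot of the target at the peak.
#' @param fs_hz sampling rate in Hz.
#' @param seed optional integer seed.
#'
#' @return an object of class `los_spec`.
#' @export
los_spec <- function(radius_target_mm = 80, dwell_s = 5,
                     control_noise_mm = 0, overshoot_frac = 0,
                     fs_hz = 40, seed = NULL) {
  if (length(radius_target_mm) == 1) radius_target_mm <- rep(radius_target_mm, 8)
  if (length(radius_target_mm) != 8 || any(radius_target_mm <= 0)) {
    stop_invalid_spec("`radius_target_mm` must be 8 positive targets (or one, recycled).")
  }
  if (dwell_s <= 0 || fs_hz <= 0) {
    stop_invalid_spec("`dwell_s` and `fs_hz` must be > 0.")
  }
  if (control_noise_mm < 0 || overshoot_frac < 0) {
    stop_invalid_spec("`control_noise_mm` and `overshoot_frac` must be >= 0.")
  }
  structure(
    list(radius_target_mm = radius_target_mm, dwell_s = dwell_s,
         control_noise_mm = control_noise_mm, overshoot_frac = overshoot_frac,
         fs_hz = fs_hz, seed = seed),
    class = "los_spec"
  )
}

#' Specification of a synthetic test-retest cohort
#'
#' Generative parameters for [gen_testretest_cohort()]. Each subject's value
#' for a variable is `mean + b + e` with `b ~ N(0, sd_between^2)` shared by
#' the subject's two sessions and `e ~ N(0, sem_within^2)` drawn per session,
#' so the true single-measures intraclass correlation is
#' `sd_between^2 / (sd_between^2 + sem_within^2)` and the true MDC95 is
#' `1.96 * sqrt(2) * sem_within`.
#'
#' @param variables data frame with columns `variable`, `mean`, `sd_between`,
#'   `sem_within` (one row per variable; an optional `task` column is carried
#'   through to the generated cohort).
#' @param n_subjects number of subjects, at least 2 (default 34, a typical
#'   reliability-study cohort size).
#' @param seed optional integer seed.
#'
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(variables, n_subjects = 34, seed = NULL) {
  variables <- as_tibble(variables)
  needed <- c("variable", "mean", "sd_between", "sem_within")
  if (!all(needed %in% names(variables))) {
    stop_invalid_spec(paste0(
      "`variables` must have columns ", paste(needed, collapse = ", "), "."))
  }
  if (!is.numeric(n_subjects) || n_subjects < 2) {
    stop_invalid_spec("`n_subjects` must be at least 2.")
  }
  if (any(variables$sd_between < 0) || any(variables$sem_within < 0)) {
    stop_invalid_spec("`sd_between` and `sem_within` must be >= 0.")
  }
  structure(
    list(variables = variables, n_subjects = as.integer(n_subjects), seed = seed),
    class = "cohort_spec"
  )
}

#' Specification of a synthetic pre/post patient measurement pair
#'
#' Generative parameters for [gen_patient_pair()]: the observed pre and post
#' values are the true states `pre_true` and `pre_true + true_change`, each
#' perturbed by independent `N(0, sem_within^2)` measurement noise.
#'
#' @param pre_true true pre-treatment value.
#' @param true_change true treatment effect (post minus pre).
#' @param sem_within standard error of measurement (>= 0).
#' @param seed optional integer seed.
#'
#' @return an object of class `patient_pair_spec`.
#' @export
patient_pair_spec <- function(pre_true, true_change, sem_within, seed = NULL) {
  if (!is.numeric(sem_within) || sem_within < 0) {
    stop_invalid_spec("`sem_within` must be >= 0.")
  }
  structure(
    list(pre_true = pre_true, true_change = true_change,
         sem_within = sem_within, seed = seed),
    class = "patient_pair_spec"
  )
}
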