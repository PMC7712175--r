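#' Octagon geometry of the limits-of-stability test
#'
#' Eight unit directions at 45-degree steps in the (ML, AP) plane, labelled
#' clockwise from Forward. Coordinate convention: ML = x (rightward
#' positive), AP = y (forward positive), origin at the platform centre.
#'
#' @param target_radius_mm target excursion per direction in mm; a single
#'   value is recycled.
#' @return tibble with columns `direction`, `ux`, `uy`, `target_mm`.
#' @examples
#' los_geometry(80)
#' @export
los_geometry <- function(target_radius_mm = 80) {
  if (length(target_radius_mm) == 1) target_radius_mm <- rep(target_radius_mm, 8)
  if (length(target_radius_mm) != 8) {
    stop_invalid_spec("`target_radius_mm` must have length 1 or 8.")
  }
  angles <- seq(0, 315, by = 45) * pi / 180 # from +AP, clockwise (towards +ML)
  tibble(
    direction = los_directions(),
    ux = round(sin(angles), 15),
    uy = round(cos(angles), 15),
    target_mm = target_radius_mm
  )
}

los_directions <- function() {
  c("Forward", "Forward-rightward", "Rightward", "Backward-rightward",
    "Backward", "Backward-leftward", "Leftward", "Forward-leftward")
}

new_cop_trajectory <- function(time_s, ml_mm, ap_mm, fs_hz, target_dir = NULL) {
  out <- tibble(time_s = time_s, ml_mm = ml_mm, ap_mm = ap_mm)
  if (!is.null(target_dir)) out$target_dir <- target_dir
  attr(out, "fs_hz") <- fs_hz
  class(out) <- c("cop_trajectory", class(out))
  out
}

# exact discretization of a stationary OU process:
#   x[t+1] = phi x[t] + sqrt(1 - phi^2) sigma z,  phi = exp(-dt/tau)
# initialized from the stationary N(0, sigma^2) law.
ou_path <- function(n, sigma, tau_s, dt) {
  if (sigma == 0) return(rep(0, n))
  phi <- exp(-dt / tau_s)
  x0 <- rnorm(1, 0, sigma)
  eps <- rnorm(n, 0, sigma * sqrt(1 - phi^2))
  as.numeric(stats::filter(eps, phi, method = "recursive", init = x0))
}

#' Simulate a quiet-stance centre-of-pressure trajectory
#'
#' Generates a 2-D stationary sway path: each coordinate is an exactly
#' discretized Ornstein-Uhlenbeck process, so the empirical SD of a long
#' recording converges to the spec's `sigma_*_mm` and every moment has a
#' closed form. This is a statistical stand-in for a platform recording, not
#' a biomechanical model.
#'
#' @param spec a [sway_spec()].
#' @return a `cop_trajectory` tibble with columns `time_s`, `ml_mm`, `ap_mm`
#'   and attribute `fs_hz`.
#' @examples
#' traj <- gen_sway_trajectory(sway_spec("RSEO", duration_s = 5, seed = 1))
#' sd(traj$ml_mm)
#' @export
gen_sway_trajectory <- function(spec) {
  if (!inherits(spec, "sway_spec")) {
    stop_invalid_spec("`spec` must be created with sway_spec().")
  }
  n <- round(spec$duration_s * spec$fs_hz)
  if (n < 2) stop_invalid_spec("spec implies fewer than 2 samples.")
  dt <- 1 / spec$fs_hz
  with_seed_if(spec$seed, {
    ml <- ou_path(n, spec$sigma_ml_mm, spec$tau_s, dt)
    ap <- ou_path(n, spec$sigma_ap_mm, spec$tau_s, dt)
    new_cop_trajectory((seq_len(n) - 1) * dt, ml, ap, spec$fs_hz)
  })
}

#' Simulate a limits-of-stability trial
#'
#' The simulated subject starts at the platform centre and performs one
#' out-and-back excursion towards each octagon direction in fixed clockwise
#' order (Forward, Forward-rightward, ..., Forward-leftward). The on-axis
#' profile is triangular with its apex exactly at
#' `radius_target_mm * (1 + overshoot_frac)`, so with zero noise and zero
#' overshoot the measured COP limit per direction equals the target exactly.
#' Gaussian tracking noise of SD `control_noise_mm` is added to both
#' coordinates.
#'
#' @param spec a [los_spec()].
#' @return a `cop_trajectory` tibble with columns `time_s`, `ml_mm`, `ap_mm`,
#'   `target_dir` (the direction being pursued at each sample).
#' @examples
#' traj <- gen_los_trajectory(los_spec(radius_target_mm = 80, dwell_s = 2))
#' max(traj$ap_mm)
#' @export
gen_los_trajectory <- function(spec) {
  if (!inherits(spec, "los_spec")) {
    stop_invalid_spec("`spec` must be created with los_spec().")
  }
  geom <- los_geometry(spec$radius_target_mm)
  n_d <- round(spec$dwell_s * spec$fs_hz)
  if (n_d < 3) stop_invalid_spec("`dwell_s * fs_hz` must give at least 3 samples per direction.")
  apex <- ceiling(n_d / 2)
  profile <- c(seq(0, 1, length.out = apex), seq(1, 0, length.out = n_d - apex + 1)[-1])
  with_seed_if(spec$seed, {
    pieces <- purrr::pmap(geom, function(direction, ux, uy, target_mm) {
      peak <- target_mm * (1 + spec$overshoot_frac)
      tibble(
        ml_mm = profile * peak * ux + rnorm(n_d, 0, spec$control_noise_mm),
        ap_mm = profile * peak * uy + rnorm(n_d, 0, spec$control_noise_mm),
        target_dir = direction
      )
    })
    path <- dplyr::bind_rows(pieces)
    # the trajectory is referenced to its own start point downstream, so the
    # first sample must be the quiet-stance centre even under noise
    path$ml_mm[1] <- 0
    path$ap_mm[1] <- 0
    new_cop_trajectory((seq_len(nrow(path)) - 1) / spec$fs_hz,
                       path$ml_mm, path$ap_mm, spec$fs_hz,
                       target_dir = path$target_dir)
  })
}

#' Simulate a test-retest reliability cohort
#'
#' Draws `n_subjects` subjects measured in two sessions (`test`, `retest`)
#' for each variable in the spec, under the additive model
#' `value = mean + b_subject + e_session` with independent Gaussian
#' components. Ground truth: single-measures ICC
#' `sd_between^2 / (sd_between^2 + sem_within^2)`, SEM `sem_within`,
#' MDC95 `1.96 * sqrt(2) * sem_within`.
#'
#' @param spec a [cohort_spec()].
#' @return tibble with columns `subject`, `session` (`"test"`/`"retest"`),
#'   `variable`, `value` (plus `task` when the spec's variable table has one).
#' @examples
#' spec <- cohort_spec(
#'   tibble::tibble(variable = "RMS", mean = 6, sd_between = 3, sem_within = 1),
#'   n_subjects = 20, seed = 1
#' )
#' gen_testretest_cohort(spec)
#' @export
gen_testretest_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) {
    stop_invalid_spec("`spec` must be created with cohort_spec().")
  }
  n <- spec$n_subjects
  subjects <- sprintf("S%02d", seq_len(n))
  vars <- spec$variables
  has_task <- "task" %in% names(vars)
  with_seed_if(spec$seed, {
    rows <- purrr::map(seq_len(nrow(vars)), function(i) {
      b <- rnorm(n, 0, vars$sd_between[i])
      row <- tibble(
        subject = rep(subjects, 2),
        session = rep(c("test", "retest"), each = n),
        variable = vars$variable[i],
        value = vars$mean[i] + rep(b, 2) + rnorm(2 * n, 0, vars$sem_within[i])
      )
      if (has_task) row <- dplyr::bind_cols(tibble(task = vars$task[i]), row)
      row
    })
    out <- dplyr::bind_rows(rows)
  })
  out
}

#' Simulate observed pre/post measurements for one patient
#'
#' @param spec a [patient_pair_spec()].
#' @param n number of independent replicate pairs to draw.
#' @return tibble with columns `draw`, `pre`, `post`.
#' @examples
#' gen_patient_pair(patient_pair_spec(10, true_change = 5, sem_within = 0))
#' @export
gen_patient_pair <- function(spec, n = 1) {
  if (!inherits(spec, "patient_pair_spec")) {
    stop_invalid_spec("`spec` must be created with patient_pair_spec().")
  }
  with_seed_if(spec$seed, {
    tibble(
      draw = seq_len(n),
      pre = spec$pre_true + rnorm(n, 0, spec$sem_within),
      post = spec$pre_true + spec$true_change + rnorm(n, 0, spec$sem_within)
    )
  })
}
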